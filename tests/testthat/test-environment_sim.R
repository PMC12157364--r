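test_that("env_protocol validates and protocol_phases expands cycles", {
  expect_error(env_protocol(c(10, -5), c(1, 0)))
  expect_error(env_protocol(10, -1))
  expect_error(env_protocol(c(10, 20), 1))
  ph <- protocol_phases(env_protocol(c(40, 400), c(3, 0), repeat_count = 3))
  expect_equal(nrow(ph), 6)
  expect_equal(ph$t_start, c(0, 40, 440, 480, 880, 920))
  expect_equal(ph$t_end, c(40, 440, 480, 880, 920, 1320))
  expect_equal(ph$A, rep(c(3, 0), 3))
  expect_equal(ph$cycle, rep(1:3, each = 2))
})

test_that("fluctuating_protocol orders phases as requested", {
  on_first <- protocol_phases(fluctuating_protocol())
  expect_equal(on_first$A[1:2], c(3, 0))
  off_first <- protocol_phases(fluctuating_protocol(on_first = FALSE))
  expect_equal(off_first$A[1:2], c(0, 3))
})

test_that("discretized_normal_init matches its definition", {
  # point mass when sd = 0
  T <- discretized_normal_init(3, 0, 10, 0.1)
  expect_equal(T[4], 0.1)
  expect_equal(sum(T), 0.1)
  # derived example: n = 2, mean 1, sd 1 -> weights prop to (e^-0.5, 1, e^-0.5)
  T2 <- discretized_normal_init(1, 1, 2, 0.1)
  w <- c(exp(-0.5), 1, exp(-0.5))
  expect_equal(T2, 0.1 * w / sum(w), tolerance = 1e-12)
  expect_equal(round(T2, 4), c(0.0274, 0.0452, 0.0274))
  # shape properties of the sweep-style initialization
  T3 <- discretized_normal_init(10, 30, 100, 0.1)
  expect_equal(sum(T3), 0.1, tolerance = 1e-12)
  expect_true(all(diff(T3[11:101]) < 0))  # decreasing past the mode
  expect_true(all(T3 > 0))
  # mean clipped into [0, n] for the point mass
  expect_equal(which(discretized_normal_init(25, 0, 10, 0.1) > 0), 11)
  expect_error(discretized_normal_init(3, 1, 10, 0), "total_density")
  expect_error(discretized_normal_init(3, 1, 10, 1.2), "total_density")
})

test_that("simulate_protocol reproduces the logistic-with-dilution limit", {
  # n = 0: dT/dt = mu T (1 - T) - d T has steady state 1 - d/mu
  p <- tcn_params(n = 0, mu_max = 1, d = 0.2, kappa_f = 0, kappa_b = 0)
  sim <- simulate_protocol(p, env_protocol(200, 0), 0.01)
  final <- sim$derived$total_density[nrow(sim$derived)]
  expect_equal(final, 1 - 0.2 / 1, tolerance = 1e-6)
})

test_that("the all-zero state stays identically zero", {
  p <- tcn_params(n = 5)
  sim <- simulate_protocol(p, env_protocol(20, 2), numeric(6))
  expect_true(all(sim$states == 0))
})

test_that("adaptive integration agrees with fixed-step RK4", {
  p <- tcn_params(n = 10)
  T0 <- discretized_normal_init(3, 2, 10, 0.1)
  prot <- env_protocol(c(25, 25), c(2, 0))
  ref <- simulate_protocol(p, prot, T0, dt = 0.01, method = "rk4")
  ada <- simulate_protocol(p, prot, T0, dt = 0.5)
  t_end <- 50
  expect_equal(state_at(ada, t_end), state_at(ref, t_end), tolerance = 1e-6)
  expect_equal(state_at(ada, 25), state_at(ref, 25), tolerance = 1e-6)
})

test_that("simulation output is stable under time-step refinement", {
  p <- tcn_params(n = 8)
  T0 <- discretized_normal_init(4, 2, 8, 0.1)
  prot <- fluctuating_protocol(gen_on = 10, gen_off = 20, cycles = 1)
  s1 <- simulate_protocol(p, prot, T0, dt = 0.5)
  s2 <- simulate_protocol(p, prot, T0, dt = 0.25)
  expect_equal(state_at(s1, 30), state_at(s2, 30), tolerance = 1e-6)
})

test_that("simulate_protocol validates the initial state and time grid", {
  p <- tcn_params(n = 3)
  prot <- env_protocol(10, 0)
  expect_error(simulate_protocol(p, prot, numeric(3)), "length")
  expect_error(simulate_protocol(p, prot, c(-0.1, 0, 0, 0)), "non-negative")
  expect_error(simulate_protocol(p, prot, c(0.5, 0.5, 0.5, 0.5)), "<= 1")
  sim <- simulate_protocol(p, prot, c(0.1, 0, 0, 0))
  expect_error(state_at(sim, 3.14), "grid")
})

test_that("trajectory invariants hold at every output time", {
  p <- tcn_params()
  T0 <- discretized_normal_init(10, 5, p$n, 0.1)
  sim <- simulate_protocol(p, fluctuating_protocol(cycles = 1), T0)
  expect_true(all(sim$states >= 0))
  expect_true(all(sim$derived$total_density <= 1 + 1e-8))
  expect_true(all(diff(sim$times) > 0))
  expect_true(all(sim$derived$mean_tcn >= 0 &
                    sim$derived$mean_tcn <= p$n))
})

test_that("mean TCN rises faster for 'both' than 'baseline' under selection", {
  p <- tcn_params()
  T0 <- discretized_normal_init(10, 5, p$n, 0.1)
  sims <- run_scenarios(p, env_protocol(40, 3), T0)
  expect_named(sims, c("baseline", "transposition_only", "both"))
  m_end <- vapply(sims, function(s) mean_tcn(state_at(s, 40)), numeric(1))
  expect_gt(m_end[["both"]], m_end[["baseline"]])
})

test_that("scenario_comparison bundles rates and fate summaries", {
  sc <- scenario_comparison()
  expect_s3_class(sc, "scenario_comparison")
  expect_equal(sc$rates$scenario,
               c("baseline", "transposition_only", "both"))
  expect_true(all(is.finite(sc$rates$gain_rate)))
  expect_true(all(is.finite(sc$rates$loss_rate)))
  expect_equal(sc$fate$initial_mean_tcn,
               rep(mean_tcn(discretized_normal_init(10, 5, 100, 0.1)), 3))
  expect_true(all(sc$fate$min_cycle_fraction <= sc$fate$final_fraction + 1e-12))
})

test_that("sweep_max_pcn flags undefined windows instead of erroring", {
  res <- sweep_max_pcn(n_values = c(10, 60), condition = "gain")
  expect_equal(names(res), c("n", "rate", "tau", "defined"))
  expect_identical(res$defined, !is.na(res$rate))
  expect_true(all(is.finite(res$tau)))
  expect_error(sweep_max_pcn(n_values = c(0, 10)), ">= 1")
})

test_that("write_sim_csv writes the two tidy tables", {
  p <- tcn_params(n = 3)
  sim <- simulate_protocol(p, env_protocol(5, 0), c(0.1, 0, 0, 0))
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  f <- write_sim_csv(sim, d)
  expect_true(all(file.exists(f)))
  long <- utils::read.csv(f[["trajectory"]])
  expect_equal(names(long), c("time", "class", "density"))
  expect_equal(nrow(long), length(sim$times) * 4)
})
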
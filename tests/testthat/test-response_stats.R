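test_that("passage_generations gives log2 of the dilution fold", {
  expect_equal(passage_generations(30000), log2(30000))
  expect_equal(round(passage_generations(30000)), 15)
  expect_equal(passage_generations(2), 1)
  expect_error(passage_generations(1), "> 1")
})

test_that("passage_schedule validates and summarizes", {
  s <- passage_schedule()
  expect_equal(s$dilution_fold, 30000)
  expect_equal(s$days_off, 5L)
  expect_equal(s$days_on, 2L)
  expect_equal(s$iterations, 3L)
  expect_error(passage_schedule(dilution_fold = 0.5))
  expect_error(passage_schedule(days_on = 0))
})

test_that("experimental gain and loss rates match the closed forms", {
  s <- passage_schedule()
  expect_equal(experimental_gain_rate(3, 3, s), 0)
  expect_equal(experimental_gain_rate(0.5, 8, s),
               log(16) / (2 * log2(30000)), tolerance = 1e-12)
  expect_equal(experimental_gain_rate(1, 2, s),
               log(2) / (2 * log2(30000)), tolerance = 1e-12)
  expect_equal(experimental_loss_rate(3, 3, s), 0)
  expect_equal(experimental_loss_rate(8, 0.5, s),
               log(16) / (5 * log2(30000)), tolerance = 1e-12)
  # increase during the off-phase gives a negative loss rate
  expect_lt(experimental_loss_rate(1, 2, s), 0)
  expect_error(experimental_gain_rate(0, 1, s), "positive")
  expect_error(experimental_loss_rate(1, -2, s), "positive")
})

test_that("rates are antisymmetric in the endpoints and scale-invariant", {
  s <- passage_schedule()
  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50); c <- runif(1, 0.5, 20)
    expect_equal(experimental_gain_rate(a, b, s),
                 -experimental_gain_rate(b, a, s), tolerance = 1e-12)
    expect_equal(experimental_gain_rate(c * a, c * b, s),
                 experimental_gain_rate(a, b, s), tolerance = 1e-12)
    # loss uses tau2 and the opposite sign of the same log fold
    expect_equal(experimental_loss_rate(a, b, s),
                 -experimental_gain_rate(a, b, s) *
                   (s$days_on / s$days_off), tolerance = 1e-12)
  }
})

test_that("sim_response_rate recovers an exact exponential construction", {
  # mean TCN 1 -> 2 while total density 0.1 -> 0.4: tau = 2, rate = ln(2)/2
  states <- rbind(c(0, 0.1, 0), c(0, 0, 0.4))
  sim <- fake_sim(times = c(0, 10), states = states)
  r <- sim_response_rate(sim, 0, 10)
  expect_equal(r$tau, 2)
  expect_equal(r$rate, log(2) / 2, tolerance = 1e-12)
  # exact exponential mean-TCN growth while density doubles each time unit
  tt <- seq(0, 5, by = 1)
  dens <- 0.005 * 2^tt           # tau over [0, 5] is exactly 5
  mtcn <- 3 * exp(0.2 * tt)      # ln fold over [0, 5] is exactly 1
  st2 <- matrix(0, length(tt), 11)
  st2[, 1] <- dens * (1 - mtcn / 10)
  st2[, 11] <- dens * mtcn / 10
  sim3 <- fake_sim(tt, st2)
  r3 <- sim_response_rate(sim3, 0, 5)
  expect_equal(r3$tau, 5)
  expect_equal(r3$rate, 1 / 5, tolerance = 1e-12)
})

test_that("sim_response_rate raises a classed condition when tau <= 0", {
  states <- rbind(c(0.2, 0.2), c(0.1, 0.1))
  sim <- fake_sim(c(0, 10), states)
  err <- tryCatch(sim_response_rate(sim, 0, 10), condition = identity)
  expect_s3_class(err, "tcndyn_undefined_rate")
  expect_equal(err$tau, -1)
  expect_match(conditionMessage(err), "did not grow")
})

test_that("average_cycle_rates computes per-cycle endpoint rates", {
  s <- passage_schedule()
  # constant series: all rates zero
  days <- 0:21
  tbl <- data.frame(replicate = 1, day = days, tcn = 5)
  rr <- average_cycle_rates(tbl, s)
  expect_s3_class(rr, "response_rates")
  expect_equal(nrow(rr$per_cycle), 3)
  expect_equal(rr$averaged$gain_rate, 0)
  expect_equal(rr$averaged$loss_rate, 0)
  # each cycle: 16-fold fall over days off, 16-fold rise over days on
  tcn <- numeric(22)
  tcn[1] <- 8
  for (d in 1:21) {
    pos <- (d - 1) %% 7 + 1
    f <- if (pos <= 5) (1 / 16)^(1 / 5) else 16^(1 / 2)
    tcn[d + 1] <- tcn[d] * f
  }
  tbl2 <- data.frame(replicate = "A", day = days, tcn = tcn)
  rr2 <- average_cycle_rates(tbl2, s)
  expect_equal(rr2$averaged$gain_rate, log(16) / (2 * log2(30000)),
               tolerance = 1e-10)
  expect_equal(rr2$averaged$loss_rate, log(16) / (5 * log2(30000)),
               tolerance = 1e-10)
  expect_equal(rr2$per_cycle$cycle, 1:3)
})

test_that("average_cycle_rates names the missing replicate and day", {
  s <- passage_schedule()
  tbl <- data.frame(replicate = "r1", day = c(0, 5), tcn = c(2, 1))
  expect_error(average_cycle_rates(tbl, s), "replicate 'r1', day 7")
})

test_that("classify_survival applies a strict 0.05 threshold", {
  expect_equal(classify_survival(c(0.049, 0.05, 0.6, 0)),
               c("failed", "survived", "survived", "failed"))
  expect_error(classify_survival(-0.1), "non-negative")
  expect_error(classify_survival(NA_real_))
})

test_that("max_od_growth_rate takes the maximum consecutive slope", {
  expect_equal(max_od_growth_rate(c(0, 2, 4), c(0.1, 0.3, 0.4)), 0.1)
  expect_equal(max_od_growth_rate(c(0, 1, 2), c(0.5, 0.5, 0.5)), 0)
  expect_lt(max_od_growth_rate(c(0, 1, 2), c(0.9, 0.5, 0.3)), 0)
  # OD window restricts the candidate pairs
  t <- 0:4
  od <- c(0.01, 0.03, 0.2, 0.8, 0.85)
  expect_equal(max_od_growth_rate(t, od), 0.6)
  expect_equal(max_od_growth_rate(t, od, od_window = c(0.02, 0.5)), 0.17)
  expect_error(max_od_growth_rate(0, 0.1), "two time points")
  expect_error(max_od_growth_rate(c(0, 0), c(1, 2)), "increasing")
  expect_error(max_od_growth_rate(t, od, od_window = c(2, 3)), "window")
})
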
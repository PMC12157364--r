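test_that("tcn_params derives kappa_f0 and kappa_bn from the primary fields", {
  p <- tcn_params(n = 100, kappa_f = 0.3, kappa_b = 0.2)
  expect_equal(p$kappa_f0, 0.3)
  expect_equal(p$kappa_bn, 0.02)
  q <- tcn_params(has_transposase = FALSE)
  expect_identical(q$kappa_f0, 0)
  r <- tcn_params(kappa_b = 0.4, kappa_bn_factor = 0.25)
  expect_equal(r$kappa_bn, 0.1)
})

test_that("tcn_params validates its inputs", {
  expect_error(tcn_params(n = -1))
  expect_error(tcn_params(n = 2.5))
  expect_error(tcn_params(beta = -0.1), "beta")
  expect_error(tcn_params(d = Inf), "'d'")
  expect_error(tcn_params(has_transposase = NA))
})

test_that("update_params recomputes derived rates and rejects unknown fields", {
  p <- tcn_params(kappa_f = 0.3)
  q <- update_params(p, has_transposase = FALSE, kappa_b = 0.6)
  expect_identical(q$kappa_f0, 0)
  expect_equal(q$kappa_bn, 0.06)
  expect_equal(q$kappa_f, p$kappa_f)
  expect_error(update_params(p, kappa_f0 = 1), "unknown parameter")
})

test_that("parameters round-trip through the YAML config", {
  p <- tcn_params(n = 17, beta = 0.012, alpha = 0.22, kappa_f = 0.19,
                  has_transposase = FALSE, d = 0.41)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  params_to_config(p, f)
  q <- params_from_config(f)
  expect_equal(q, p)
})

test_that("ec50 follows (1 + alpha i) gamma", {
  expect_equal(ec50(0, tcn_params(gamma = 1.5)), 1.5)
  expect_equal(ec50(7, tcn_params(alpha = 0, gamma = 2)), 2)
  expect_equal(ec50(10, tcn_params(alpha = 0.1, gamma = 1)), 2)
  expect_error(ec50(-1, tcn_params()), "integer in")
  expect_error(ec50(101, tcn_params(n = 100)), "integer in")
})

test_that("max_growth declines linearly and clamps at zero", {
  p <- tcn_params(mu_max = 1, beta = 0.005)
  expect_equal(max_growth(0, p), 1)
  expect_equal(max_growth(100, p), 0.5)
  expect_warning(m <- max_growth(60, tcn_params(mu_max = 1, beta = 0.02)),
                 "clamp")
  expect_identical(m, 0)
  # strictly decreasing until the clamp
  i <- 0:100
  m <- max_growth(i, p)
  expect_true(all(diff(m) < 0))
})

test_that("growth_rate is Hill-inhibited with coefficient 2", {
  p <- tcn_params(mu_max = 1, beta = 0.005, alpha = 0.1, gamma = 1)
  expect_equal(growth_rate(0, 0, p), 1)
  expect_equal(growth_rate(10, 2, p), 0.95 * 4 / 8)
  i <- 37
  expect_equal(growth_rate(i, ec50(i, p), p), max_growth(i, p) / 2)
  # Hill factor increasing in i at fixed A > 0
  g <- growth_rate(0:100, 1.7, p) / max_growth(0:100, p)
  expect_true(all(diff(g) > 0))
  expect_error(growth_rate(0, -1, p), "non-negative")
})

test_that("ode_rhs reproduces the hand-expanded n = 1 boundary rows", {
  p <- tcn_params(n = 1, mu_max = 0, kappa_f = 0.3, kappa_b = 0.2, d = 0)
  dT <- ode_rhs(c(0.5, 0.3), 0, p)
  expect_equal(dT, c(-0.0288, 0.0288), tolerance = 1e-12)
})

test_that("ode_rhs has extinction as a fixed point and validates shape", {
  p <- tcn_params(n = 4)
  expect_identical(ode_rhs(numeric(5), 2, p), numeric(5))
  expect_error(ode_rhs(numeric(4), 2, p), "length")
})

test_that("transitions conserve total density when mu = 0, d = 0", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(1:12, 1)
    p <- tcn_params(n = n, mu_max = 0, d = 0,
                    kappa_f = runif(1, 0, 0.5), kappa_b = runif(1, 0, 0.5),
                    has_transposase = sample(c(TRUE, FALSE), 1))
    T <- runif(n + 1); T <- 0.9 * T / sum(T)
    expect_lt(abs(sum(ode_rhs(T, runif(1, 0, 5), p))), 1e-12)
  }
})

test_that("ode_rhs matches the independent small-n oracle on random draws", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(1:3, 1)
    p <- tcn_params(
      n = n, mu_max = runif(1, 0.5, 1.5), beta = runif(1, 0, 0.2),
      alpha = runif(1, 0, 0.5), gamma = runif(1, 0.5, 2),
      kappa_f = runif(1, 0, 0.5), kappa_b = runif(1, 0, 0.5),
      has_transposase = sample(c(TRUE, FALSE), 1),
      kappa_bn_factor = runif(1, 0, 1), d = runif(1, 0, 0.6))
    T <- runif(n + 1); T <- runif(1, 0.1, 0.95) * T / sum(T)
    A <- runif(1, 0, 6)
    expect_equal(ode_rhs(T, A, p), oracle_rhs_small_n(T, A, p),
                 tolerance = 1e-12)
  }
})

test_that("scenario presets carry the three transition configurations", {
  b <- scenario_preset("baseline")
  expect_equal(b[c("kappa_f", "kappa_b")], list(kappa_f = 0.1, kappa_b = 0.1))
  expect_false(b$has_transposase)
  t1 <- scenario_preset("transposition_only")
  expect_equal(t1[c("kappa_f", "kappa_b")],
               list(kappa_f = 0.15, kappa_b = 0.1))
  expect_true(t1$has_transposase)
  t2 <- scenario_preset("both")
  expect_equal(t2[c("kappa_f", "kappa_b")], list(kappa_f = 0.3, kappa_b = 0.2))
  expect_true(t2$has_transposase)
  expect_error(scenario_preset("nope"))
})

test_that("mean_tcn and total_tcn behave on simple states", {
  expect_equal(mean_tcn(c(0, 0, 0.3, 0)), 2)
  expect_equal(mean_tcn(c(0.2, 0, 0.2)), 1)
  expect_equal(mean_tcn(c(0.1, 0.2, 0.3, 0.4)), 2)
  expect_equal(total_tcn(c(0.1, 0.2, 0.3, 0.4)), 2)
  expect_error(mean_tcn(numeric(3)), "empty")
})
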
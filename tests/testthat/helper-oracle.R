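# Hand-expanded right-hand sides for small n, written independently of
# ode_rhs so the two implementations can be compared term by term.

oracle_rhs_n1 <- function(T, A, p) {
  mu <- sapply(0:1, function(i) {
    ec <- (1 + p$alpha * i) * p$gamma
    max(0, p$mu_max * (1 - p$beta * i)) * ec^2 / (A^2 + ec^2)
  })
  log_fac <- 1 - sum(T)
  kbn <- p$kappa_bn_factor * p$kappa_b
  kf0 <- if (p$has_transposase) p$kappa_f else 0
  d0 <- (mu[1] * T[1] - kf0 * T[1] + kbn * T[2]) * log_fac - p$d * T[1]
  d1 <- (mu[2] * T[2] + kf0 * T[1] - kbn * T[2]) * log_fac - p$d * T[2]
  c(d0, d1)
}

oracle_rhs_n2 <- function(T, A, p) {
  mu <- sapply(0:2, function(i) {
    ec <- (1 + p$alpha * i) * p$gamma
    max(0, p$mu_max * (1 - p$beta * i)) * ec^2 / (A^2 + ec^2)
  })
  log_fac <- 1 - sum(T)
  kbn <- p$kappa_bn_factor * p$kappa_b
  kf0 <- if (p$has_transposase) p$kappa_f else 0
  kf <- p$kappa_f; kb <- p$kappa_b
  d0 <- (mu[1] * T[1] - kf0 * T[1] + kb * T[2]) * log_fac - p$d * T[1]
  d1 <- (mu[2] * T[2] + kf0 * T[1] + kbn * T[3] -
           (kf + kb) * T[2]) * log_fac - p$d * T[2]
  d2 <- (mu[3] * T[3] + kf * T[2] - kbn * T[3]) * log_fac - p$d * T[3]
  c(d0, d1, d2)
}

oracle_rhs_n3 <- function(T, A, p) {
  mu <- sapply(0:3, function(i) {
    ec <- (1 + p$alpha * i) * p$gamma
    max(0, p$mu_max * (1 - p$beta * i)) * ec^2 / (A^2 + ec^2)
  })
  log_fac <- 1 - sum(T)
  kbn <- p$kappa_bn_factor * p$kappa_b
  kf0 <- if (p$has_transposase) p$kappa_f else 0
  kf <- p$kappa_f; kb <- p$kappa_b
  d0 <- (mu[1] * T[1] - kf0 * T[1] + kb * T[2]) * log_fac - p$d * T[1]
  d1 <- (mu[2] * T[2] + kf0 * T[1] + kb * T[3] -
           (kf + kb) * T[2]) * log_fac - p$d * T[2]
  d2 <- (mu[3] * T[3] + kf * T[2] + kbn * T[4] -
           (kf + kb) * T[3]) * log_fac - p$d * T[3]
  d3 <- (mu[4] * T[4] + kf * T[3] - kbn * T[4]) * log_fac - p$d * T[4]
  c(d0, d1, d2, d3)
}

oracle_rhs_small_n <- function(T, A, p) {
  switch(as.character(p$n),
         "1" = oracle_rhs_n1(T, A, p),
         "2" = oracle_rhs_n2(T, A, p),
         "3" = oracle_rhs_n3(T, A, p),
         stop("oracle only covers n in 1..3"))
}

# A minimal fake "tcn_sim" with prescribed times and state rows, for testing
# rate computations in isolation from the integrator.
fake_sim <- function(times, states) {
  structure(list(times = times, states = states), class = "tcn_sim")
}
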
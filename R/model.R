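#' Half-inhibition antibiotic concentration of a TCN class
#'
#' EC50 of the subpopulation carrying `i` transposon copies:
#' `EC_i = (1 + alpha * i) * gamma`. Each additional copy of the resistance
#' cargo raises the concentration needed to halve growth by a constant
#' fraction `alpha` of the baseline `gamma`.
#'
#' @param i TCN class index (vectorized), 0 <= i <= n.
#' @param params A [tcn_params()] object.
#' @return EC50 value(s), same length as `i`.
#' @export
ec50 <- function(i, params) {
  check_class_index(i, params)
  (1 + params$alpha * i) * params$gamma
}

#' Antibiotic-free maximum growth rate of a TCN class
#'
#' `mu_i_max = mu_max * (1 - beta * i)`: growth declines linearly with copy
#' number to account for transposon burden. The linear form can go negative
#' for large `beta * i`; negative intrinsic growth is not part of the model,
#' so the value is clamped at zero (with a warning when the clamp engages).
#'
#' @inheritParams ec50
#' @return Maximum specific growth rate(s), per generation.
#' @export
max_growth <- function(i, params) {
  check_class_index(i, params)
  m <- params$mu_max * (1 - params$beta * i)
  if (any(m < 0)) {
    warning("growth burden beta*i exceeds 1 for some classes; ",
            "clamping mu_i_max at 0", call. = FALSE)
    m <- pmax(m, 0)
  }
  m
}

#' Growth rate of a TCN class at antibiotic concentration A
#'
#' `mu_i = mu_i_max * EC_i^2 / (A^2 + EC_i^2)`: burden-reduced maximum growth
#' times a Hill inhibition factor with coefficient 2. At `A = 0` growth equals
#' `max_growth(i)`; at `A = ec50(i)` it is exactly half of that.
#'
#' @inheritParams ec50
#' @param A Antibiotic concentration, >= 0 (scalar).
#' @return Growth rate(s), per generation.
#' @export
growth_rate <- function(i, A, params) {
  check_class_index(i, params)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0) {
    stop("'A' must be a single non-negative concentration", call. = FALSE)
  }
  ec <- ec50(i, params)
  max_growth(i, params) * ec^2 / (A^2 + ec^2)
}

#' Right-hand side of the TCN subpopulation ODE system
#'
#' For the state vector `T = (T_0, ..., T_n)` of subpopulation densities
#' (fractions of a shared carrying capacity of 1), the derivative of class
#' `i` is
#'
#' `dT_i/dt = (mu_i T_i + inflow_i - outflow_i) * (1 - sum_j T_j) - d T_i`
#'
#' where the logistic factor multiplies the whole bracket (growth and
#' transitions both require cell division) and the transition fluxes are
#' flux-conservative:
#' * forward out of class `i` at rate `kappa_f` (class 0 uses `kappa_f0`;
#'   class `n` has no forward exit),
#' * backward out of class `i` at rate `kappa_b` (class `n` uses `kappa_bn`;
#'   class 0 has no backward exit),
#' * each exit flux enters the adjacent class, so with all `mu_i = 0` and
#'   `d = 0` the derivatives sum exactly to zero.
#'
#' @param T Numeric vector of length `n + 1`, non-negative, sum <= 1.
#' @param A Antibiotic concentration, >= 0.
#' @param params A [tcn_params()] object.
#' @return Numeric vector of derivatives, length `n + 1`.
#' @export
ode_rhs <- function(T, A, params) {
  stopifnot(inherits(params, "tcn_params"))
  np1 <- params$n + 1L
  if (length(T) != np1) {
    stop(sprintf("state has length %d but n = %d requires length %d",
                 length(T), params$n, np1), call. = FALSE)
  }
  mu <- growth_rate(0:params$n, A, params)
  # per-class exit rates; entries feed the neighbouring class
  kf_out <- rep(params$kappa_f, np1)
  kf_out[1L] <- params$kappa_f0
  kf_out[np1] <- 0
  kb_out <- rep(params$kappa_b, np1)
  kb_out[1L] <- 0
  if (np1 > 1L) kb_out[np1] <- params$kappa_bn
  fwd <- kf_out * T     # flux i -> i+1
  bwd <- kb_out * T     # flux i -> i-1
  inflow <- c(0, fwd[-np1]) + c(bwd[-1L], 0)
  bracket <- mu * T - fwd - bwd + inflow
  bracket * (1 - sum(T)) - params$d * T
}

#' Transition-rate presets for the three modelled scenarios
#'
#' The scenario comparison uses three (kappa_f, kappa_b) configurations:
#' a baseline with neither transposition nor plasmid copy number dynamics
#' beyond basal random segregation (0.1, 0.1); transposition without PCN
#' dynamics (0.15, 0.1); and both mechanisms (0.3, 0.2). Biologically, the
#' baseline corresponds to a transposase-free strain, so it also carries
#' `has_transposase = FALSE`; the other two scenarios have a functional
#' transposase.
#'
#' @param name One of `"baseline"`, `"transposition_only"`, `"both"`.
#' @return A named list with `kappa_f`, `kappa_b`, `has_transposase`.
#' @export
scenario_preset <- function(name = c("baseline", "transposition_only", "both")) {
  name <- match.arg(name)
  switch(name,
    baseline           = list(kappa_f = 0.1,  kappa_b = 0.1, has_transposase = FALSE),
    transposition_only = list(kappa_f = 0.15, kappa_b = 0.1, has_transposase = TRUE),
    both               = list(kappa_f = 0.3,  kappa_b = 0.2, has_transposase = TRUE)
  )
}

#' Per-cell mean transposon copy number of a state
#'
#' `sum(i * T_i) / sum(T_i)`: the population-average TCN, the simulation
#' analogue of a qPCR copy-number-per-genome measurement.
#'
#' @param T Numeric state vector (density by TCN class, starting at class 0).
#' @return Mean TCN, in `[0, length(T) - 1]`.
#' @export
mean_tcn <- function(T) {
  stopifnot(is.numeric(T), length(T) >= 1L, all(T >= 0))
  tot <- sum(T)
  if (tot <= 0) {
    stop("empty population: sum(T) must be > 0 to define a mean TCN",
         call. = FALSE)
  }
  sum((seq_along(T) - 1) * T) / tot
}

#' Total transposon copies per unit carrying capacity
#'
#' `sum(i * T_i)`: the population-total copy load, exposed as an alternate
#' series alongside the per-cell mean.
#'
#' @inheritParams mean_tcn
#' @return Total TCN density.
#' @export
total_tcn <- function(T) {
  stopifnot(is.numeric(T), length(T) >= 1L, all(T >= 0))
  sum((seq_along(T) - 1) * T)
}

check_class_index <- function(i, params) {
  stopifnot(inherits(params, "tcn_params"))
  if (!is.numeric(i) || any(!is.finite(i)) || any(i != round(i)) ||
      any(i < 0) || any(i > params$n)) {
    stop(sprintf("class index i must be an integer in [0, %d]", params$n),
         call. = FALSE)
  }
  invisible(TRUE)
}
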
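#' Model parameters for the TCN subpopulation model
#'
#' Bundles every constant of the coarse-grained transposon copy number (TCN)
#' model: a population with a maximum plasmid copy number `n` is split into
#' `n + 1` subpopulations indexed by their TCN `i` (0..n). Growth is logistic
#' with Hill-type antibiotic inhibition; transposition and plasmid copy number
#' dynamics move density between adjacent TCN classes.
#'
#' Two rates are derived, never set directly, so the parameter surface stays
#' minimal:
#' * `kappa_f0`, the T0 -> T1 rate, equals `kappa_f` when a chromosomal
#'   transposase is present (`has_transposase = TRUE`) and 0 otherwise —
#'   without a transposase the transposon-free class cannot regain a copy.
#' * `kappa_bn`, the Tn -> Tn-1 rate, equals `kappa_bn_factor * kappa_b`
#'   (default factor 0.1): loss from the fully loaded class requires a failed
#'   cut-and-paste event, which is rarer than ordinary backward transitions.
#'
#' @param n Maximum plasmid copy number per cell (= maximum TCN); integer
#'   >= 0.
#' @param mu_max Maximum specific growth rate of the transposon-free
#'   subpopulation, per generation.
#' @param beta Fractional growth-rate cost per transposon copy
#'   (dimensionless).
#' @param alpha Fractional increase of the half-inhibition antibiotic
#'   concentration per transposon copy (dimensionless).
#' @param gamma Baseline half-inhibition antibiotic concentration (the EC50
#'   of the transposon-free class), in concentration units.
#' @param kappa_f Forward transition rate Ti -> Ti+1, per generation.
#' @param kappa_b Backward transition rate Ti -> Ti-1, per generation.
#' @param has_transposase Logical; is a (single-copy, chromosomal)
#'   transposase present, enabling the T0 -> T1 transition?
#' @param kappa_bn_factor Multiplier giving the Tn -> Tn-1 rate as
#'   `kappa_bn_factor * kappa_b`; default 0.1.
#' @param d Dilution rate, per generation.
#'
#' @return An object of class `"tcn_params"`: a list with the supplied fields
#'   plus the derived `kappa_f0` and `kappa_bn`.
#' @examples
#' p <- tcn_params(n = 100, kappa_f = 0.3, kappa_b = 0.2)
#' p$kappa_f0  # equals kappa_f: transposase present by default
#' p$kappa_bn  # 0.1 * kappa_b
#' @export
tcn_params <- function(n = 100,
                       mu_max = 1,
                       beta = 0.008,
                       alpha = 0.3,
                       gamma = 1,
                       kappa_f = 0.3,
                       kappa_b = 0.2,
                       has_transposase = TRUE,
                       kappa_bn_factor = 0.1,
                       d = 0.5) {
  stopifnot(length(n) == 1L, is.numeric(n), n >= 0, n == round(n))
  for (nm in c("mu_max", "beta", "alpha", "gamma", "kappa_f", "kappa_b",
               "kappa_bn_factor", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative finite number", nm),
           call. = FALSE)
    }
  }
  stopifnot(is.logical(has_transposase), length(has_transposase) == 1L,
            !is.na(has_transposase))
  p <- structure(
    list(
      n = as.integer(n),
      mu_max = mu_max, beta = beta, alpha = alpha, gamma = gamma,
      kappa_f = kappa_f, kappa_b = kappa_b,
      has_transposase = has_transposase,
      kappa_bn_factor = kappa_bn_factor,
      d = d,
      kappa_f0 = if (has_transposase) kappa_f else 0,
      kappa_bn = kappa_bn_factor * kappa_b
    ),
    class = "tcn_params"
  )
  p
}

#' @export
print.tcn_params <- function(x, ...) {
  cat("TCN model parameters\n")
  cat(sprintf("  n (max PCN = max TCN): %d  (%d subpopulations)\n",
              x$n, x$n + 1L))
  cat(sprintf("  growth: mu_max = %g, beta = %g (burden/copy)\n",
              x$mu_max, x$beta))
  cat(sprintf("  inhibition: gamma = %g, alpha = %g (EC50 gain/copy)\n",
              x$gamma, x$alpha))
  cat(sprintf("  transitions: kappa_f = %g, kappa_b = %g, kappa_f0 = %g, kappa_bn = %g\n",
              x$kappa_f, x$kappa_b, x$kappa_f0, x$kappa_bn))
  cat(sprintf("  transposase: %s;  dilution d = %g\n",
              if (x$has_transposase) "present" else "absent", x$d))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; derived rates
#' (`kappa_f0`, `kappa_bn`) are recomputed.
#'
#' @param params A [tcn_params()] object.
#' @param ... Named fields to replace (any constructor argument).
#' @return A new `"tcn_params"` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "tcn_params"))
  upd <- list(...)
  keep <- c("n", "mu_max", "beta", "alpha", "gamma", "kappa_f", "kappa_b",
            "has_transposase", "kappa_bn_factor", "d")
  bad <- setdiff(names(upd), keep)
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- utils::modifyList(params[keep], upd)
  do.call(tcn_params, args)
}

#' Serialize / deserialize parameters as a config block
#'
#' `params_to_config()` writes the parameter set to a YAML file (or returns
#' the YAML string when `file = NULL`); `params_from_config()` reads one back.
#' Only the ten primary fields are stored — derived rates are recomputed on
#' read, so a config can never carry an inconsistent `kappa_f0` or `kappa_bn`.
#'
#' @param params A [tcn_params()] object.
#' @param file Path to write/read; `NULL` in `params_to_config` returns the
#'   YAML text.
#' @return `params_from_config` returns a `"tcn_params"` object.
#' @export
params_to_config <- function(params, file = NULL) {
  stopifnot(inherits(params, "tcn_params"))
  x <- params[c("n", "mu_max", "beta", "alpha", "gamma", "kappa_f",
                "kappa_b", "has_transposase", "kappa_bn_factor", "d")]
  txt <- yaml::as.yaml(x)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' @rdname params_to_config
#' @export
params_from_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(tcn_params, x)
}
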
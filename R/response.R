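#' Serial-passage schedule
#'
#' Describes the fluctuating serial-passage design: each day the culture is
#' diluted `dilution_fold`-fold into fresh medium, allowing
#' `log2(dilution_fold)` generations of regrowth; each iteration consists of
#' `days_off` days without antibiotic followed by `days_on` days with it, and
#' the whole pattern repeats `iterations` times (defaults: 30,000-fold
#' dilution, 5 days off / 2 days on, 3 iterations — a 21-day experiment).
#'
#' @param dilution_fold Daily dilution factor, > 1 (default 30000).
#' @param days_off Days without antibiotic per iteration (default 5).
#' @param days_on Days with antibiotic per iteration (default 2).
#' @param iterations Number of off/on iterations (default 3).
#' @return An object of class `"passage_schedule"`.
#' @export
passage_schedule <- function(dilution_fold = 30000, days_off = 5L,
                             days_on = 2L, iterations = 3L) {
  stopifnot(is.numeric(dilution_fold), length(dilution_fold) == 1L,
            dilution_fold > 1,
            days_off >= 1, days_off == round(days_off),
            days_on >= 1, days_on == round(days_on),
            iterations >= 1, iterations == round(iterations))
  structure(
    list(dilution_fold = dilution_fold,
         days_off = as.integer(days_off),
         days_on = as.integer(days_on),
         iterations = as.integer(iterations)),
    class = "passage_schedule"
  )
}

#' @export
print.passage_schedule <- function(x, ...) {
  cat(sprintf(
    "Passage schedule: %g-fold daily dilution (%.2f generations/day),\n",
    x$dilution_fold, passage_generations(x$dilution_fold)))
  cat(sprintf("  %d iterations of %d days off / %d days on (%d days total)\n",
              x$iterations, x$days_off, x$days_on, total_days(x)))
  invisible(x)
}

total_days <- function(schedule) {
  schedule$iterations * (schedule$days_off + schedule$days_on)
}

#' Generations of regrowth per passage
#'
#' A `fold`-fold dilution followed by regrowth back to the original density
#' corresponds to `log2(fold)` doublings; for the standard 30,000-fold
#' passage this is ~15 generations.
#'
#' @param dilution_fold Dilution factor, > 1.
#' @return Generations per passage, `log2(dilution_fold)`.
#' @export
passage_generations <- function(dilution_fold) {
  if (!is.numeric(dilution_fold) || any(dilution_fold <= 1)) {
    stop("'dilution_fold' must be > 1", call. = FALSE)
  }
  log2(dilution_fold)
}

check_tcn_pair <- function(tcn_start, tcn_end) {
  if (!is.numeric(tcn_start) || !is.numeric(tcn_end) ||
      any(!is.finite(tcn_start)) || any(!is.finite(tcn_end)) ||
      any(tcn_start <= 0) || any(tcn_end <= 0)) {
    stop("TCN endpoints must be positive and finite (low-copy qPCR values ",
         "at or below zero cannot enter a log rate)", call. = FALSE)
  }
}

#' Experimental transposon gain rate over a selection window
#'
#' Per-generation log change of TCN across the antibiotic-on window:
#' `(1 / tau1) * ln(tcn_end / tcn_start)` with
#' `tau1 = days_on * log2(dilution_fold)` generations (for the default
#' schedule, `2 * log2(30000)`).
#'
#' @param tcn_start,tcn_end TCN (or GFP/OD surrogate) at the window start
#'   (e.g. day 5) and end (e.g. day 7); must be > 0.
#' @param schedule A [passage_schedule()].
#' @return Gain rate, per generation (positive when TCN increased).
#' @export
experimental_gain_rate <- function(tcn_start, tcn_end,
                                   schedule = passage_schedule()) {
  stopifnot(inherits(schedule, "passage_schedule"))
  check_tcn_pair(tcn_start, tcn_end)
  tau1 <- schedule$days_on * passage_generations(schedule$dilution_fold)
  log(tcn_end / tcn_start) / tau1
}

#' Experimental transposon loss rate over a no-selection window
#'
#' Per-generation log change of TCN across the antibiotic-off window with the
#' sign flipped so that faster loss is more positive:
#' `-(1 / tau2) * ln(tcn_end / tcn_start)` with
#' `tau2 = days_off * log2(dilution_fold)` generations (for the default
#' schedule, `5 * log2(30000)`).
#'
#' @inheritParams experimental_gain_rate
#' @return Loss rate, per generation (positive when TCN decreased).
#' @export
experimental_loss_rate <- function(tcn_start, tcn_end,
                                   schedule = passage_schedule()) {
  stopifnot(inherits(schedule, "passage_schedule"))
  check_tcn_pair(tcn_start, tcn_end)
  tau2 <- schedule$days_off * passage_generations(schedule$dilution_fold)
  -log(tcn_end / tcn_start) / tau2
}

#' Simulation response rate between two trajectory times
#'
#' The simulation analogue of the experimental rates:
#' `(1 / tau) * ln(meanTCN(t_end) / meanTCN(t0))` where the elapsed
#' generation count is taken from the population's own growth,
#' `tau = log2(total_density(t_end) / total_density(t0))`. When the
#' population did not grow over the window (`tau <= 0`) the rate is
#' undefined and a condition of class `"tcndyn_undefined_rate"` carrying
#' `tau` is raised; callers such as [sweep_max_pcn()] map it to a flagged
#' row.
#'
#' @param result A `"tcn_sim"` from [simulate_protocol()].
#' @param t0,t_end Window endpoints; must lie on the stored time grid with
#'   `t0 < t_end`.
#' @return List with `rate` (per generation) and `tau` (generations).
#' @export
sim_response_rate <- function(result, t0, t_end) {
  stopifnot(inherits(result, "tcn_sim"), t0 < t_end)
  s0 <- state_at(result, t0)
  s1 <- state_at(result, t_end)
  d0 <- sum(s0); d1 <- sum(s1)
  if (d0 <= 0 || d1 <= 0) {
    stop("population density must be positive at both window endpoints",
         call. = FALSE)
  }
  tau <- log2(d1 / d0)
  if (tau <= 0) {
    cond <- structure(
      class = c("tcndyn_undefined_rate", "error", "condition"),
      list(message = sprintf(
        "response rate undefined: population did not grow over the window (tau = %.4g)",
        tau), call = sys.call(-1), tau = tau)
    )
    stop(cond)
  }
  m0 <- mean_tcn(s0); m1 <- mean_tcn(s1)
  if (m0 <= 0 || m1 <= 0) {
    stop("mean TCN must be positive at both window endpoints", call. = FALSE)
  }
  list(rate = log(m1 / m0) / tau, tau = tau)
}

#' Per-cycle gain/loss rates from a daily TCN table
#'
#' Takes a tidy table of per-day TCN measurements (columns `replicate`,
#' `day`, `tcn`; day 0 is the pre-passage measurement) and, for each
#' replicate and each iteration of the schedule, computes the loss rate over
#' the off-window endpoints (day `7k` to day `7k + days_off` for the default
#' schedule) and the gain rate over the on-window endpoints (day
#' `7k + days_off` to day `7(k+1)`), then averages across iterations.
#' Intermediate days are not fitted — only the window endpoints enter, as in
#' the printed rate formulas.
#'
#' @param tcn_by_day data.frame with columns `replicate`, `day`, `tcn`.
#' @param schedule A [passage_schedule()].
#' @return An object of class `"response_rates"`: list with `per_cycle`
#'   (data.frame: replicate, cycle, gain_rate, loss_rate) and `averaged`
#'   (data.frame: replicate, gain_rate, loss_rate — means over cycles).
#' @export
average_cycle_rates <- function(tcn_by_day, schedule = passage_schedule()) {
  stopifnot(is.data.frame(tcn_by_day),
            all(c("replicate", "day", "tcn") %in% names(tcn_by_day)),
            inherits(schedule, "passage_schedule"))
  cyc_len <- schedule$days_off + schedule$days_on
  reps <- unique(tcn_by_day$replicate)
  get_tcn <- function(rep, day) {
    v <- tcn_by_day$tcn[tcn_by_day$replicate == rep & tcn_by_day$day == day]
    if (length(v) != 1L || is.na(v)) {
      stop(sprintf("missing TCN value for replicate '%s', day %d", rep, day),
           call. = FALSE)
    }
    v
  }
  rows <- list()
  for (rep in reps) {
    for (k in seq_len(schedule$iterations)) {
      d0 <- (k - 1L) * cyc_len
      d_mid <- d0 + schedule$days_off
      d_end <- k * cyc_len
      loss <- experimental_loss_rate(get_tcn(rep, d0), get_tcn(rep, d_mid),
                                     schedule)
      gain <- experimental_gain_rate(get_tcn(rep, d_mid), get_tcn(rep, d_end),
                                     schedule)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, cycle = k, gain_rate = gain, loss_rate = loss
      )
    }
  }
  per_cycle <- do.call(rbind, rows)
  averaged <- do.call(rbind, lapply(split(per_cycle, per_cycle$replicate),
    function(df) data.frame(replicate = df$replicate[1],
                            gain_rate = mean(df$gain_rate),
                            loss_rate = mean(df$loss_rate))))
  rownames(averaged) <- NULL
  structure(list(per_cycle = per_cycle, averaged = averaged),
            class = "response_rates")
}

#' @export
print.response_rates <- function(x, ...) {
  cat("Per-replicate response rates (averaged over cycles):\n")
  print(x$averaged, row.names = FALSE)
  invisible(x)
}

#' Survival classification from endpoint OD600
#'
#' A replicate fails when its culture density stays below the detection
#' threshold: `od600 < 0.05` (strictly) is classified `"failed"`, otherwise
#' `"survived"`.
#'
#' @param od600 Optical density value(s), >= 0.
#' @return Character vector of `"survived"` / `"failed"`.
#' @export
classify_survival <- function(od600) {
  if (!is.numeric(od600) || any(!is.finite(od600)) || any(od600 < 0)) {
    stop("'od600' must be non-negative and finite", call. = FALSE)
  }
  ifelse(od600 < 0.05, "failed", "survived")
}

#' Maximum OD-difference growth-rate estimate
#'
#' The growth rate of a batch growth curve, estimated as the maximum slope
#' over consecutive measurement pairs: `max (od[k+1] - od[k]) /
#' (t[k+1] - t[k])`, in OD units per hour. With every-other-hour sampling
#' the difference is divided by the actual 2 h gap, because "per hour" is a
#' rate. The exponential-phase restriction can be enforced with an OD window:
#' only pairs whose two OD values both lie inside `od_window` are considered
#' (off by default, since no bounds are inherent to the estimator).
#'
#' @param times_h Strictly increasing measurement times, hours.
#' @param od OD600 values, same length.
#' @param od_window Optional numeric length-2 OD window, e.g. `c(0.05, 0.8)`.
#' @return Maximum slope, OD per hour (negative if the series only falls).
#' @export
max_od_growth_rate <- function(times_h, od, od_window = NULL) {
  stopifnot(is.numeric(times_h), is.numeric(od),
            length(times_h) == length(od))
  if (length(times_h) < 2L) {
    stop("at least two time points are required", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("'times_h' must be strictly increasing", call. = FALSE)
  }
  slopes <- diff(od) / diff(times_h)
  if (!is.null(od_window)) {
    stopifnot(is.numeric(od_window), length(od_window) == 2L)
    inside <- od >= od_window[1] & od <= od_window[2]
    keep <- inside[-length(inside)] & inside[-1]
    slopes <- slopes[keep]
    if (!length(slopes)) {
      stop("no consecutive pair lies inside the OD window", call. = FALSE)
    }
  }
  max(slopes)
}
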
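#' Antibiotic environment protocol
#'
#' An ordered list of phases, each with a duration (in generations) and a
#' constant antibiotic concentration, repeated `repeat_count` times. The
#' concentration is piecewise-constant in time; the integrator restarts at
#' each phase boundary rather than stepping across the discontinuity.
#'
#' @param durations Numeric vector of phase durations, generations, > 0.
#' @param A Numeric vector of antibiotic concentrations per phase, >= 0,
#'   same length as `durations`.
#' @param repeat_count Number of times the phase list is repeated (cycles).
#' @return An object of class `"env_protocol"`.
#' @export
env_protocol <- function(durations, A, repeat_count = 1L) {
  stopifnot(is.numeric(durations), is.numeric(A),
            length(durations) == length(A), length(durations) >= 1L,
            all(is.finite(durations)), all(durations > 0),
            all(is.finite(A)), all(A >= 0),
            length(repeat_count) == 1L, repeat_count >= 1,
            repeat_count == round(repeat_count))
  structure(
    list(durations = as.numeric(durations), A = as.numeric(A),
         repeat_count = as.integer(repeat_count)),
    class = "env_protocol"
  )
}

#' Default fluctuating-selection protocol
#'
#' Three cycles of antibiotic selection, each followed by a long period
#' without selection, on the model's continuous (generation) time axis:
#' each cycle is `gen_on` generations at `A_sel` followed by `gen_off`
#' generations at `A = 0` (defaults 40 and 400). Cycles start with the
#' selection phase, matching the simulated fluctuating-environment
#' comparison (selection, each followed by a period of no selection); set
#' `on_first = FALSE` for the reverse order.
#'
#' The default selection strength is `A_sel = 3 * gamma`: strong enough to
#' suppress low-TCN classes, while high-TCN classes still outgrow the
#' dilution rate so the selection window is informative rather than lethal.
#' The long no-selection phase gives the purifying dynamics time to act.
#'
#' @param A_sel Antibiotic concentration during selection phases.
#' @param gen_on,gen_off Phase lengths in generations (defaults 40 and 400).
#' @param cycles Number of cycles (default 3).
#' @param on_first Logical; selection phase first within each cycle?
#' @return An `"env_protocol"`.
#' @export
fluctuating_protocol <- function(A_sel = 3, gen_on = 40, gen_off = 400,
                                 cycles = 3L, on_first = TRUE) {
  if (on_first) {
    env_protocol(c(gen_on, gen_off), c(A_sel, 0), repeat_count = cycles)
  } else {
    env_protocol(c(gen_off, gen_on), c(0, A_sel), repeat_count = cycles)
  }
}

#' Expand a protocol into a phase table
#'
#' @param protocol An [env_protocol()].
#' @return A data.frame with columns `phase`, `cycle`, `t_start`, `t_end`,
#'   `A`.
#' @export
protocol_phases <- function(protocol) {
  stopifnot(inherits(protocol, "env_protocol"))
  dur <- rep(protocol$durations, protocol$repeat_count)
  A <- rep(protocol$A, protocol$repeat_count)
  ends <- cumsum(dur)
  data.frame(
    phase = seq_along(dur),
    cycle = rep(seq_len(protocol$repeat_count), each = length(protocol$A)),
    t_start = c(0, ends[-length(ends)]),
    t_end = ends,
    A = A
  )
}

#' Discretized truncated-normal initial state
#'
#' Builds a `PopulationState` by evaluating a normal density with the given
#' mean and standard deviation at the integer TCN classes 0..n, normalizing
#' the weights to sum to one, and scaling by `total_density`. This is the
#' initialization used for the maximum-PCN sweep: selection ("gain")
#' conditions start near the minimum TCN (mean 10 copies, sd 30% of n) and
#' no-selection ("loss") conditions near the maximum (mean 90% of n, sd 30%
#' of n). With `sd = 0` (or numerically zero) all mass is placed at
#' `round(mean)` clipped into `[0, n]`.
#'
#' @param mean Mean of the generating normal, in copies.
#' @param sd Standard deviation, in copies, >= 0.
#' @param n Maximum TCN (state has `n + 1` classes).
#' @param total_density Total initial density in (0, 1].
#' @return Numeric vector of length `n + 1` summing to `total_density`.
#' @export
discretized_normal_init <- function(mean, sd, n, total_density = 0.1) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0,
            is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  if (!is.numeric(total_density) || length(total_density) != 1L ||
      !is.finite(total_density) || total_density <= 0 || total_density > 1) {
    stop("'total_density' must lie in (0, 1]", call. = FALSE)
  }
  i <- 0:n
  if (sd < 1e-9) {
    T <- numeric(n + 1L)
    T[min(max(round(mean), 0), n) + 1L] <- total_density
    return(T)
  }
  w <- stats::dnorm(i, mean = mean, sd = sd)
  if (sum(w) <= 0) stop("normal weights vanished on [0, n]", call. = FALSE)
  total_density * w / sum(w)
}

rhs_desolve <- function(t, y, parms) {
  list(ode_rhs(y, parms$A, parms$params))
}

#' Integrate the TCN model under an environment protocol
#'
#' Integrates the subpopulation ODE system phase by phase: within each phase
#' the antibiotic concentration is constant and the adaptive solver
#' (`deSolve::ode`, lsoda by default) runs from the phase start to its end;
#' the final state seeds the next phase, so the trajectory is continuous
#' while `A(t)` jumps. Small negative densities from integrator round-off
#' (above `-1e-10`) are clipped to zero; anything lower aborts with an
#' integration error naming the phase.
#'
#' @param params A [tcn_params()] object.
#' @param protocol An [env_protocol()].
#' @param T0 Initial state, length `n + 1`, non-negative, sum <= 1.
#' @param dt Output time step, generations (default 0.5).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method `deSolve` method name (default `"lsoda"`).
#' @return An object of class `"tcn_sim"`: list with `times`, `states`
#'   (matrix time x class), `A_of_t`, `params`, `protocol`, and a `derived`
#'   data.frame (`time`, `total_density`, `mean_tcn`, `total_tcn`, `A`).
#' @export
simulate_protocol <- function(params, protocol, T0,
                              dt = 0.5, rtol = 1e-8, atol = 1e-10,
                              method = "lsoda") {
  stopifnot(inherits(params, "tcn_params"), inherits(protocol, "env_protocol"))
  np1 <- params$n + 1L
  if (length(T0) != np1) {
    stop(sprintf("T0 has length %d, expected n + 1 = %d", length(T0), np1),
         call. = FALSE)
  }
  if (any(T0 < 0) || sum(T0) > 1 + 1e-9) {
    stop("T0 must be non-negative with total density <= 1", call. = FALSE)
  }
  phases <- protocol_phases(protocol)
  times_all <- numeric(0)
  states_all <- NULL
  A_all <- numeric(0)
  y <- as.numeric(T0)
  for (k in seq_len(nrow(phases))) {
    t0 <- phases$t_start[k]; t1 <- phases$t_end[k]
    tt <- seq(t0, t1, by = dt)
    if (tt[length(tt)] < t1) tt <- c(tt, t1)
    sol <- deSolve::ode(
      y = y, times = tt, func = rhs_desolve,
      parms = list(A = phases$A[k], params = params),
      method = method, rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("integration failed in phase %d (A = %g)", k, phases$A[k]),
           call. = FALSE)
    }
    st <- unname(sol[, -1, drop = FALSE])
    if (any(st < -1e-10)) {
      stop(sprintf("integration produced negative densities in phase %d", k),
           call. = FALSE)
    }
    st[st < 0] <- 0
    # drop the duplicated phase-boundary point except for the first phase
    keep <- if (k == 1L) seq_len(nrow(st)) else seq(2L, nrow(st))
    times_all <- c(times_all, sol[keep, 1])
    states_all <- rbind(states_all, st[keep, , drop = FALSE])
    A_all <- c(A_all, rep(phases$A[k], length(keep)))
    y <- st[nrow(st), ]
  }
  colnames(states_all) <- paste0("T", 0:params$n)
  tot <- rowSums(states_all)
  mt <- ifelse(tot > 0,
               as.numeric(states_all %*% (0:params$n)) / tot, NA_real_)
  structure(
    list(
      times = times_all,
      states = states_all,
      A_of_t = A_all,
      params = params,
      protocol = protocol,
      derived = data.frame(
        time = times_all,
        total_density = tot,
        mean_tcn = mt,
        total_tcn = as.numeric(states_all %*% (0:params$n)),
        A = A_all
      )
    ),
    class = "tcn_sim"
  )
}

#' @export
print.tcn_sim <- function(x, ...) {
  cat(sprintf("TCN simulation: n = %d, %d time points over %g generations\n",
              x$params$n, length(x$times), max(x$times)))
  dd <- x$derived
  cat(sprintf("  final total density %.4g, final mean TCN %.4g\n",
              dd$total_density[nrow(dd)], dd$mean_tcn[nrow(dd)]))
  invisible(x)
}

state_at <- function(result, t) {
  idx <- which.min(abs(result$times - t))
  if (abs(result$times[idx] - t) > 1e-6 + 1e-9 * abs(t)) {
    stop(sprintf("time %g is not on the stored grid", t), call. = FALSE)
  }
  result$states[idx, ]
}

#' Run the three scenario presets on identical inputs
#'
#' Applies each [scenario_preset()] to `base_params` (replacing `kappa_f`,
#' `kappa_b` and `has_transposase`) and simulates all three under the same
#' protocol and initial state, so the results are directly comparable.
#'
#' @param base_params A [tcn_params()] object fixing everything except the
#'   transition rates and transposase flag.
#' @param protocol An [env_protocol()].
#' @param T0 Initial state shared by all scenarios.
#' @param ... Passed to [simulate_protocol()].
#' @return Named list of `"tcn_sim"` objects
#'   (`baseline`, `transposition_only`, `both`).
#' @export
run_scenarios <- function(base_params, protocol, T0, ...) {
  scen <- c("baseline", "transposition_only", "both")
  out <- lapply(scen, function(s) {
    ps <- scenario_preset(s)
    p <- update_params(base_params, kappa_f = ps$kappa_f,
                       kappa_b = ps$kappa_b,
                       has_transposase = ps$has_transposase)
    simulate_protocol(p, protocol, T0, ...)
  })
  names(out) <- scen
  out
}

#' Gain/loss response rates of a simulated fluctuating run
#'
#' For each cycle of the protocol, computes the simulation response rate
#' ([sim_response_rate()]) over the selection window (gain) and the
#' no-selection window (loss, sign-flipped so that faster transposon loss is
#' more positive), then averages across the cycles where the rate is defined.
#' A window's rate is defined only when the total population density grew
#' over the window (the generation count `tau = log2(density fold)` must be
#' positive); windows starting from a saturated culture under selection
#' typically shrink and are flagged `NA`.
#'
#' @param result A `"tcn_sim"` from a protocol with exactly two phases per
#'   cycle, one at `A = 0` and one at `A > 0`.
#' @return List with `per_cycle` (data.frame: cycle, gain_rate, loss_rate,
#'   tau_gain, tau_loss) and `gain_rate`/`loss_rate` averages over defined
#'   cycles.
#' @export
scenario_response_rates <- function(result) {
  stopifnot(inherits(result, "tcn_sim"))
  phases <- protocol_phases(result$protocol)
  if (length(unique(phases$A)) < 2)
    stop("protocol has no alternation between selection and no selection",
         call. = FALSE)
  rate_or_na <- function(t0, t1, flip) {
    r <- tryCatch(sim_response_rate(result, t0, t1),
                  tcndyn_undefined_rate = function(e) {
                    list(rate = NA_real_, tau = e$tau)
                  })
    if (flip && !is.na(r$rate)) r$rate <- -r$rate
    r
  }
  cycles <- unique(phases$cycle)
  rows <- lapply(cycles, function(cy) {
    ph <- phases[phases$cycle == cy, ]
    on <- ph[ph$A > 0, ][1, ]
    off <- ph[ph$A == 0, ][1, ]
    g <- rate_or_na(on$t_start, on$t_end, flip = FALSE)
    l <- rate_or_na(off$t_start, off$t_end, flip = TRUE)
    data.frame(cycle = cy, gain_rate = g$rate, loss_rate = l$rate,
               tau_gain = g$tau, tau_loss = l$tau)
  })
  per_cycle <- do.call(rbind, rows)
  list(
    per_cycle = per_cycle,
    gain_rate = mean(per_cycle$gain_rate, na.rm = TRUE),
    loss_rate = mean(per_cycle$loss_rate, na.rm = TRUE)
  )
}

#' Full scenario comparison with default inputs
#'
#' Convenience wrapper reproducing the modelled scenario comparison in one
#' call: runs the three [scenario_preset()]s under a common fluctuating
#' protocol from a common initial state (by default a discretized normal
#' with mean 10 copies, sd 5, total density 0.1 — a mostly low-copy
#' population entering its first selection phase), then summarizes each run.
#'
#' @param base_params A [tcn_params()] fixing everything except the
#'   scenario-controlled fields.
#' @param protocol An [env_protocol()] (default [fluctuating_protocol()]).
#' @param T0 Shared initial state; default
#'   `discretized_normal_init(10, 5, base_params$n, 0.1)`.
#' @param ... Passed to [simulate_protocol()].
#' @return An object of class `"scenario_comparison"`: list with `sims`
#'   (the three `"tcn_sim"` objects), `rates` (data.frame: scenario,
#'   gain_rate, loss_rate, averaged over defined cycles) and `fate`
#'   (data.frame: scenario, initial/final mean TCN, `final_fraction`, and
#'   `min_cycle_fraction`, the minimum over cycle-end mean TCN divided by
#'   the initial mean TCN).
#' @export
scenario_comparison <- function(base_params = tcn_params(),
                                protocol = fluctuating_protocol(),
                                T0 = NULL, ...) {
  stopifnot(inherits(base_params, "tcn_params"),
            inherits(protocol, "env_protocol"))
  if (is.null(T0)) {
    T0 <- discretized_normal_init(10, 5, base_params$n, 0.1)
  }
  sims <- run_scenarios(base_params, protocol, T0, ...)
  m0 <- mean_tcn(T0)
  phases <- protocol_phases(protocol)
  cycle_ends <- tapply(phases$t_end, phases$cycle, max)
  rates <- do.call(rbind, lapply(names(sims), function(s) {
    r <- scenario_response_rates(sims[[s]])
    data.frame(scenario = s, gain_rate = r$gain_rate, loss_rate = r$loss_rate)
  }))
  fate <- do.call(rbind, lapply(names(sims), function(s) {
    sim <- sims[[s]]
    mt_end <- vapply(cycle_ends, function(t) mean_tcn(state_at(sim, t)),
                     numeric(1))
    data.frame(scenario = s, initial_mean_tcn = m0,
               final_mean_tcn = mt_end[length(mt_end)],
               final_fraction = mt_end[length(mt_end)] / m0,
               min_cycle_fraction = min(mt_end / m0))
  }))
  structure(list(sims = sims, rates = rates, fate = fate),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (rates averaged over defined cycles):\n")
  print(x$rates, row.names = FALSE)
  cat("Transposon fate (mean TCN relative to initial):\n")
  print(x$fate, row.names = FALSE)
  invisible(x)
}

#' Sweep the maximum plasmid copy number
#'
#' Simulates populations with maximum PCN `n` over a grid (default 10 to 100
#' in steps of 5) and computes the simulation response rate for each. The
#' `condition` selects both the environment and the initial composition:
#' * `"gain"` — constant selection (`A = A_sel`) for `gen_on` generations,
#'   starting from a discretized normal with mean `gain_mean` (10 copies)
#'   and sd `0.3 * n`;
#' * `"loss"` — no antibiotic for `gen_off` generations, starting from mean
#'   `0.9 * n`, sd `0.3 * n` (loss rates are sign-flipped so faster loss is
#'   more positive).
#'
#' Rows where the population shrank over the window (generation count
#' `tau <= 0`, e.g. when the dilution rate exceeds the maximum growth rate of
#' a small-`n` population under selection) are flagged `defined = FALSE` with
#' `rate = NA` rather than raising an error; this produces the discontinuous
#' jump of response speed versus maximum PCN in the gain condition.
#'
#' @param n_values Integer grid of maximum PCN values (default
#'   `seq(10, 100, by = 5)`).
#' @param condition `"gain"` or `"loss"`.
#' @param base_params A [tcn_params()]; its `n` is replaced per grid point.
#' @param A_sel Selection concentration for the gain condition (default 5:
#'   at this dose the default dilution rate `d = 0.5` exceeds the maximum
#'   growth rate of small-`n` populations, producing the discontinuity).
#' @param gen_on,gen_off Window lengths in generations (defaults 40, 400,
#'   matching the default fluctuating protocol's phases).
#' @param gain_mean Mean initial TCN in the gain condition (default 10).
#' @param sd_frac,loss_mean_frac Initial sd and loss-condition mean as
#'   fractions of `n` (defaults 0.3 and 0.9).
#' @param total_density Initial total density (default 0.1).
#' @param ... Passed to [simulate_protocol()].
#' @return data.frame with columns `n`, `rate`, `tau`, `defined`.
#' @export
sweep_max_pcn <- function(n_values = seq(10L, 100L, by = 5L),
                          condition = c("gain", "loss"),
                          base_params = tcn_params(),
                          A_sel = 5, gen_on = 40, gen_off = 400,
                          gain_mean = 10, sd_frac = 0.3,
                          loss_mean_frac = 0.9, total_density = 0.1, ...) {
  condition <- match.arg(condition)
  if (any(n_values < 1)) stop("all n values must be >= 1", call. = FALSE)
  rows <- lapply(n_values, function(n) {
    p <- update_params(base_params, n = as.integer(n))
    if (condition == "gain") {
      T0 <- discretized_normal_init(gain_mean, sd_frac * n, n, total_density)
      prot <- env_protocol(gen_on, A_sel)
    } else {
      T0 <- discretized_normal_init(loss_mean_frac * n, sd_frac * n, n,
                                    total_density)
      prot <- env_protocol(gen_off, 0)
    }
    sim <- simulate_protocol(p, prot, T0, ...)
    r <- tryCatch(sim_response_rate(sim, 0, max(sim$times)),
                  tcndyn_undefined_rate = function(e) {
                    list(rate = NA_real_, tau = e$tau)
                  })
    rate <- r$rate
    if (condition == "loss" && !is.na(rate)) rate <- -rate
    data.frame(n = n, rate = rate, tau = r$tau, defined = !is.na(rate))
  })
  do.call(rbind, rows)
}

#' Write a simulation result to tidy CSV files
#'
#' Writes a long trajectory table (`time`, `class`, `density`) and the
#' derived-series table (`time`, `total_density`, `mean_tcn`, `total_tcn`,
#' `A`).
#'
#' @param result A `"tcn_sim"`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_sim_csv <- function(result, dir, prefix = "sim") {
  stopifnot(inherits(result, "tcn_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- data.frame(
    time = rep(result$times, times = ncol(result$states)),
    class = rep(0:(ncol(result$states) - 1L), each = length(result$times)),
    density = as.vector(result$states)
  )
  f1 <- file.path(dir, paste0(prefix, "_trajectory.csv"))
  f2 <- file.path(dir, paste0(prefix, "_derived.csv"))
  utils::write.csv(long, f1, row.names = FALSE)
  utils::write.csv(result$derived, f2, row.names = FALSE)
  invisible(c(trajectory = f1, derived = f2))
}
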
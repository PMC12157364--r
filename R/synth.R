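#' Serial-passage experiment design
#'
#' The layout of a synthetic fluctuating-selection experiment: a passage
#' schedule (default 5 days off / 2 days on, 3 iterations, 30,000-fold daily
#' dilution), a number of replicates per strain, a strain table and the
#' antibiotic concentrations of the two phases. Strains differ by their
#' typical maximum plasmid copy number `n` and by whether a chromosomal
#' transposase is present.
#'
#' The default on-phase concentration is `1.5 * gamma`, emulating the
#' experimental choice of an antibiotic dose low enough that resistant
#' subpopulations complete the full ~15 generations of daily regrowth while
#' transposon-free cells are strongly suppressed.
#'
#' @param schedule A [passage_schedule()].
#' @param replicates Replicates per strain (default 5).
#' @param strains data.frame with columns `label`, `n`, `has_transposase`.
#' @param A_on,A_off Antibiotic concentration in selection / no-selection
#'   phases.
#' @param init_mean_frac,init_sd_frac Initial TCN distribution: discretized
#'   normal with mean `init_mean_frac * n` and sd `init_sd_frac * n`
#'   (defaults 0.9 and 0.3 — cultures enter the experiment loaded with
#'   transposons).
#' @param init_density Day-0 total density (default 0.5, a dense overnight
#'   culture).
#' @param od_scale OD600 at carrying capacity (default 1.0; cancels in GFP/OD
#'   and in all log-ratio rates).
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(schedule = passage_schedule(),
                              replicates = 5L,
                              strains = data.frame(
                                label = "pUC", n = 100L,
                                has_transposase = TRUE),
                              A_on = 1.5, A_off = 0,
                              init_mean_frac = 0.9, init_sd_frac = 0.3,
                              init_density = 0.5, od_scale = 1.0) {
  stopifnot(inherits(schedule, "passage_schedule"),
            replicates >= 1, replicates == round(replicates),
            is.data.frame(strains),
            all(c("label", "n", "has_transposase") %in% names(strains)),
            A_on >= 0, A_off >= 0, init_density > 0, init_density <= 1,
            od_scale > 0)
  structure(
    list(schedule = schedule, replicates = as.integer(replicates),
         strains = strains, A_on = A_on, A_off = A_off,
         init_mean_frac = init_mean_frac, init_sd_frac = init_sd_frac,
         init_density = init_density, od_scale = od_scale),
    class = "experiment_design"
  )
}

#' Observation noise model for synthetic experiments
#'
#' Plate-reader and qPCR noise applied to the simulated truth:
#' OD600 and GFP/OD receive multiplicative log-normal noise
#' (`x * exp(N(0, sd))`), Ct values additive Gaussian noise in cycles.
#' With all sds at zero every observable is an exact deterministic transform
#' of the trajectory. Defaults (GFP 0.1, Ct 0.1 cycles, OD 0.05) are
#' plausible plate-reader/qPCR magnitudes, stated as defaults rather than
#' truths.
#'
#' @param gfp_gain GFP units per transposon copy per OD (proportionality
#'   constant; cancels in all rate computations).
#' @param gfp_lognormal_sd Log-sd of the GFP/OD noise.
#' @param ct_gaussian_sd Sd of the Ct noise, cycles.
#' @param od_lognormal_sd Log-sd of the OD noise.
#' @param ref_ct Noiseless Ct of the single-copy chromosomal reference
#'   target (anchors the Ct scale).
#' @param seed Integer RNG seed.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(gfp_gain = 1000, gfp_lognormal_sd = 0.1,
                        ct_gaussian_sd = 0.1, od_lognormal_sd = 0.05,
                        ref_ct = 20, seed = 1L) {
  stopifnot(gfp_gain > 0, gfp_lognormal_sd >= 0, ct_gaussian_sd >= 0,
            od_lognormal_sd >= 0, is.finite(ref_ct),
            length(seed) == 1L, seed == round(seed))
  structure(
    list(gfp_gain = gfp_gain, gfp_lognormal_sd = gfp_lognormal_sd,
         ct_gaussian_sd = ct_gaussian_sd, od_lognormal_sd = od_lognormal_sd,
         ref_ct = ref_ct, seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Invert the relative-quantification formula to a Ct value
#'
#' Returns the Ct at which a target with amplification factor `af` reports
#' `copies` copies relative to a reference sitting at `ct_at_unit`:
#' `ct = ct_at_unit - log(copies) / log(af)`, so that
#' `af^ct_at_unit / af^ct = copies`. When the reference primer pair has a
#' different amplification factor `af_ref`, pass
#' `ct_at_unit = ct_ref * log(af_ref) / log(af)`.
#'
#' @param copies Copy number relative to the reference, > 0.
#' @param af Amplification factor of the target primers, > 1.
#' @param ct_at_unit Ct at which the target would report one copy.
#' @return Ct value.
#' @export
ct_from_copies <- function(copies, af, ct_at_unit) {
  if (!is.numeric(copies) || any(!is.finite(copies)) || any(copies <= 0)) {
    stop("'copies' must be positive", call. = FALSE)
  }
  if (!is.numeric(af) || any(af <= 1)) {
    stop("'af' must exceed 1", call. = FALSE)
  }
  ct_at_unit - log(copies) / log(af)
}

# Integrate one batch day: instantaneous dilution then regrowth with d = 0
# for log2(dilution_fold) generations at constant A.
batch_day <- function(T, A, params, gen_per_day, rtol = 1e-8, atol = 1e-12) {
  y <- T / 1 # copy
  p0 <- update_params(params, d = 0)
  sol <- deSolve::ode(
    y = y, times = c(0, gen_per_day), func = rhs_desolve,
    parms = list(A = A, params = p0), method = "lsoda",
    rtol = rtol, atol = atol
  )
  st <- sol[nrow(sol), -1]
  st[st < 0 & st > -1e-10] <- 0
  if (any(st < 0)) stop("batch-day integration produced negative densities",
                        call. = FALSE)
  unname(st)
}

# Antibiotic concentration on day d (1-based) of the schedule.
day_concentration <- function(day, schedule, A_on, A_off) {
  cyc_len <- schedule$days_off + schedule$days_on
  pos <- (day - 1L) %% cyc_len + 1L
  if (pos <= schedule$days_off) A_off else A_on
}

#' Generate a synthetic serial-passage experiment
#'
#' Runs the subpopulation model in daily batch mode — each day the state is
#' divided by the dilution fold and then integrated (with `d = 0`) for
#' `log2(dilution_fold)` generations at that day's antibiotic concentration —
#' and emits, for every strain, replicate and day:
#' * `plate_table`: `od600 = total_density * od_scale` and
#'   `gfp_over_od = gfp_gain * mean_tcn`, both under log-normal noise, plus a
#'   `failed` flag set from the first day the replicate's density falls below
#'   the extinction floor (1e-12);
#' * `ct_table`: Ct values for the reference, plasmid and transposon targets
#'   obtained by inverting the relative-quantification formulas at the truth
#'   copy numbers (transposon copies per genome include the chromosomal copy
#'   for transposase strains) plus Gaussian Ct noise;
#' * `truth_table`: the exact noiseless trajectory (`mean_tcn`, `mean_pcn`,
#'   `total_density`).
#'
#' The coarse-grained model does not track the plasmid copy number itself,
#' so the truth `mean_pcn` is emitted as the strain's typical `n`, constant
#' over time.
#'
#' Within a strain the deterministic trajectory is shared by all replicates;
#' replicates differ only through observation noise. All randomness derives
#' from `noise$seed`, so identical inputs give identical tables.
#'
#' @param params A [tcn_params()]; `n` and `has_transposase` are overridden
#'   per strain.
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @return An object of class `"synthetic_experiment"`: list with
#'   `plate_table`, `ct_table`, `truth_table`, `design`, `noise`, `params`.
#' @export
generate_experiment <- function(params = tcn_params(),
                                design = experiment_design(),
                                noise = noise_model()) {
  stopifnot(inherits(params, "tcn_params"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  sched <- design$schedule
  n_days <- total_days(sched)
  gen_day <- passage_generations(sched$dilution_fold)
  floor_density <- 1e-12
  set.seed(noise$seed)
  plate <- list(); cts <- list(); truth <- list()
  for (s in seq_len(nrow(design$strains))) {
    lab <- as.character(design$strains$label[s])
    n <- as.integer(design$strains$n[s])
    has_tn <- isTRUE(design$strains$has_transposase[s])
    p <- update_params(params, n = n, has_transposase = has_tn)
    cal <- default_calibrations(
      if (has_tn) "with_transposase" else "without_transposase")
    af_ref <- cal$reference$amplification_factor
    chrom <- if (has_tn) 1L else 0L
    # deterministic daily trajectory, shared by replicates
    T <- discretized_normal_init(design$init_mean_frac * n,
                                 design$init_sd_frac * n, n,
                                 design$init_density)
    dens <- numeric(n_days + 1L); mtcn <- numeric(n_days + 1L)
    dens[1L] <- sum(T); mtcn[1L] <- mean_tcn(T)
    for (day in seq_len(n_days)) {
      A_day <- day_concentration(day, sched, design$A_on, design$A_off)
      T <- batch_day(T / sched$dilution_fold, A_day, p, gen_day)
      dens[day + 1L] <- sum(T)
      mtcn[day + 1L] <- if (sum(T) > 0) mean_tcn(T) else NA_real_
    }
    failed_from <- which(dens < floor_density)[1]
    days <- 0:n_days
    for (r in seq_len(design$replicates)) {
      failed <- if (is.na(failed_from)) rep(FALSE, n_days + 1L)
                else days >= (failed_from - 1L)
      od <- dens * design$od_scale *
        exp(stats::rnorm(n_days + 1L, 0, noise$od_lognormal_sd))
      gfp <- noise$gfp_gain * mtcn *
        exp(stats::rnorm(n_days + 1L, 0, noise$gfp_lognormal_sd))
      plate[[length(plate) + 1L]] <- data.frame(
        strain = lab, replicate = r, day = days,
        od600 = od, gfp_over_od = gfp, failed = failed
      )
      ct_ref <- noise$ref_ct +
        stats::rnorm(n_days + 1L, 0, noise$ct_gaussian_sd)
      tcn_copies <- mtcn + chrom
      ct_tet <- ct_from_copies(
        tcn_copies, cal$transposon$amplification_factor,
        noise$ref_ct * log(af_ref) / log(cal$transposon$amplification_factor)
      ) + stats::rnorm(n_days + 1L, 0, noise$ct_gaussian_sd)
      ct_kan <- ct_from_copies(
        rep(n, n_days + 1L), cal$plasmid$amplification_factor,
        noise$ref_ct * log(af_ref) / log(cal$plasmid$amplification_factor)
      ) + stats::rnorm(n_days + 1L, 0, noise$ct_gaussian_sd)
      cts[[length(cts) + 1L]] <- data.frame(
        strain = lab,
        replicate = rep(r, 3L * (n_days + 1L)),
        day = rep(days, 3L),
        target = rep(c(cal$reference$target, cal$plasmid$target,
                       cal$transposon$target), each = n_days + 1L),
        ct = c(ct_ref, ct_kan, ct_tet)
      )
      truth[[length(truth) + 1L]] <- data.frame(
        strain = lab, replicate = r, day = days,
        mean_tcn = mtcn, mean_pcn = n, total_density = dens
      )
    }
  }
  structure(
    list(
      plate_table = do.call(rbind, plate),
      ct_table = do.call(rbind, cts),
      truth_table = do.call(rbind, truth),
      design = design, noise = noise, params = params
    ),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic serial-passage experiment: %d strain(s) x %d replicates x %d days\n",
    nrow(x$design$strains), x$design$replicates,
    total_days(x$design$schedule)))
  cat(sprintf("  seed %d; tables: plate (%d rows), ct (%d rows), truth (%d rows)\n",
              x$noise$seed, nrow(x$plate_table), nrow(x$ct_table),
              nrow(x$truth_table)))
  invisible(x)
}

#' Write a synthetic experiment to CSV files plus a JSON manifest
#'
#' @param experiment A `"synthetic_experiment"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- c(plate = file.path(dir, "plate_table.csv"),
         ct = file.path(dir, "ct_table.csv"),
         truth = file.path(dir, "truth_table.csv"),
         manifest = file.path(dir, "manifest.json"))
  utils::write.csv(experiment$plate_table, f[["plate"]], row.names = FALSE)
  utils::write.csv(experiment$ct_table, f[["ct"]], row.names = FALSE)
  utils::write.csv(experiment$truth_table, f[["truth"]], row.names = FALSE)
  manifest <- list(
    params = unclass(experiment$params),
    schedule = unclass(experiment$design$schedule),
    design = list(
      replicates = experiment$design$replicates,
      strains = experiment$design$strains,
      A_on = experiment$design$A_on, A_off = experiment$design$A_off,
      init_mean_frac = experiment$design$init_mean_frac,
      init_sd_frac = experiment$design$init_sd_frac,
      init_density = experiment$design$init_density,
      od_scale = experiment$design$od_scale
    ),
    noise = unclass(experiment$noise)
  )
  jsonlite::write_json(manifest, f[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(f)
}

rates_from_tcn_table <- function(tbl, schedule) {
  res <- average_cycle_rates(tbl, schedule)
  res$averaged
}

#' End-to-end parameter recovery study
#'
#' Generates `n_repeats` synthetic datasets (seeds `noise$seed + 0:(k-1)`),
#' runs the analysis pipeline on the noisy observables — qPCR quantification
#' of the Ct table ([quantify_ct_table()]) and the GFP/OD surrogate — and
#' compares the per-replicate cycle-averaged gain/loss rates against the
#' rates computed from the noiseless truth table. Also compares survival
#' calls ([classify_survival()] on noisy OD600) against the truth density.
#'
#' @param params,design,noise As for [generate_experiment()].
#' @param n_repeats Number of independent datasets (default 1).
#' @return An object of class `"recovery_report"`: list with `rates` (one
#'   row per repeat x strain x replicate x estimator with truth and
#'   estimated gain/loss rates) and `summary` (per estimator: bias, RMSE,
#'   mean absolute error and mean absolute error relative to the mean truth
#'   magnitude, separately for gain and loss), plus `survival_agreement`,
#'   the fraction of (day, replicate) survival calls matching truth.
#' @export
recovery_study <- function(params = tcn_params(),
                           design = experiment_design(),
                           noise = noise_model(),
                           n_repeats = 1L) {
  stopifnot(n_repeats >= 1, n_repeats == round(n_repeats))
  sched <- design$schedule
  all_rows <- list()
  surv_match <- 0L; surv_total <- 0L
  for (k in seq_len(n_repeats)) {
    nk <- noise
    nk$seed <- noise$seed + k - 1L
    ex <- generate_experiment(params, design, nk)
    for (s in seq_len(nrow(design$strains))) {
      lab <- as.character(design$strains$label[s])
      has_tn <- isTRUE(design$strains$has_transposase[s])
      cal <- default_calibrations(
        if (has_tn) "with_transposase" else "without_transposase")
      chrom <- if (has_tn) 1L else 0L
      truth_s <- ex$truth_table[ex$truth_table$strain == lab, ]
      plate_s <- ex$plate_table[ex$plate_table$strain == lab, ]
      ct_s <- ex$ct_table[ex$ct_table$strain == lab, ]
      truth_rates <- rates_from_tcn_table(
        data.frame(replicate = truth_s$replicate, day = truth_s$day,
                   tcn = truth_s$mean_tcn), sched)
      q <- quantify_ct_table(ct_s, cal, chromosomal_copies = chrom)
      qpcr_rates <- rates_from_tcn_table(
        data.frame(replicate = q$replicate, day = q$day, tcn = q$tcn), sched)
      gfp_rates <- rates_from_tcn_table(
        data.frame(replicate = plate_s$replicate, day = plate_s$day,
                   tcn = plate_s$gfp_over_od), sched)
      for (est in c("qpcr", "gfp")) {
        er <- if (est == "qpcr") qpcr_rates else gfp_rates
        m <- merge(truth_rates, er, by = "replicate",
                   suffixes = c("_truth", "_est"))
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          repeat_id = k, strain = lab, estimator = est,
          replicate = m$replicate,
          gain_truth = m$gain_rate_truth, gain_est = m$gain_rate_est,
          loss_truth = m$loss_rate_truth, loss_est = m$loss_rate_est
        )
      }
      truth_surv <- classify_survival(
        pmin(truth_s$total_density * design$od_scale, 10))
      est_surv <- classify_survival(pmin(plate_s$od600, 10))
      surv_match <- surv_match + sum(truth_surv == est_surv)
      surv_total <- surv_total + length(truth_surv)
    }
  }
  rates <- do.call(rbind, all_rows)
  summarize <- function(truth, est) {
    err <- est - truth
    c(bias = mean(err), rmse = sqrt(mean(err^2)),
      mean_abs_error = mean(abs(err)),
      rel_abs_error = mean(abs(err)) / mean(abs(truth)))
  }
  summ <- do.call(rbind, lapply(split(rates, rates$estimator), function(df) {
    g <- summarize(df$gain_truth, df$gain_est)
    l <- summarize(df$loss_truth, df$loss_est)
    data.frame(estimator = df$estimator[1],
               window = c("gain", "loss"),
               bias = c(g["bias"], l["bias"]),
               rmse = c(g["rmse"], l["rmse"]),
               mean_abs_error = c(g["mean_abs_error"], l["mean_abs_error"]),
               rel_abs_error = c(g["rel_abs_error"], l["rel_abs_error"]))
  }))
  rownames(summ) <- NULL
  structure(
    list(rates = rates, summary = summ,
         survival_agreement = surv_match / surv_total),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Pipeline recovery report\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Survival-call agreement with truth: %.1f%%\n",
              100 * x$survival_agreement))
  invisible(x)
}
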
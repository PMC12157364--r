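#' Amplification factor from a standard-curve slope
#'
#' For a qPCR standard curve of Ct against log10 dilution, the per-cycle
#' template fold-increase is `AF = 10^(-1 / slope)`. A perfectly efficient
#' primer pair doubles the template each cycle (slope -3.32, AF 2).
#'
#' @param slope Standard-curve slope, Ct per log10 dilution; must be < 0.
#' @return Amplification factor, > 1 for any finite negative slope.
#' @export
amplification_factor <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope >= 0)) {
    stop("'slope' must be negative (Ct decreases as template increases)",
         call. = FALSE)
  }
  10^(-1 / slope)
}

#' Primer efficiency from an amplification factor (and back)
#'
#' `efficiency = (AF - 1) * 100` percent; 100% means perfect doubling.
#' `af_from_efficiency()` inverts the relation: `AF = 1 + efficiency / 100`.
#'
#' @param af Amplification factor, > 0.
#' @return Efficiency in percent.
#' @export
primer_efficiency <- function(af) {
  if (!is.numeric(af) || any(!is.finite(af)) || any(af <= 0)) {
    stop("'af' must be positive", call. = FALSE)
  }
  (af - 1) * 100
}

#' @rdname primer_efficiency
#' @param efficiency_percent Primer efficiency in percent.
#' @export
af_from_efficiency <- function(efficiency_percent) {
  if (!is.numeric(efficiency_percent) || any(!is.finite(efficiency_percent))) {
    stop("'efficiency_percent' must be finite", call. = FALSE)
  }
  1 + efficiency_percent / 100
}

#' Primer calibration record
#'
#' Holds the standard-curve calibration of one primer pair. Exactly one of
#' `slope`, `amplification_factor` or `efficiency_percent` must be supplied;
#' the other representations are derived (`AF = 10^(-1/slope)`,
#' `efficiency = (AF - 1) * 100`).
#'
#' @param target Target label (free-form, e.g. `"cmR"`, `"dxs"`, `"kanR"`,
#'   `"tetA"`).
#' @param slope Standard-curve slope (Ct per log10 dilution, negative).
#' @param amplification_factor Per-cycle fold increase, > 1.
#' @param efficiency_percent Efficiency in percent.
#' @return An object of class `"primer_calibration"`.
#' @export
primer_calibration <- function(target, slope = NULL,
                               amplification_factor = NULL,
                               efficiency_percent = NULL) {
  supplied <- !c(is.null(slope), is.null(amplification_factor),
                 is.null(efficiency_percent))
  if (sum(supplied) != 1L) {
    stop("supply exactly one of 'slope', 'amplification_factor', ",
         "'efficiency_percent'", call. = FALSE)
  }
  if (!is.null(slope)) {
    if (!is.numeric(slope) || !is.finite(slope) || slope >= 0) {
      stop("'slope' must be negative", call. = FALSE)
    }
    af <- 10^(-1 / slope)
  } else if (!is.null(amplification_factor)) {
    stopifnot(amplification_factor > 1)
    af <- amplification_factor
    slope <- -1 / log10(af)
  } else {
    af <- af_from_efficiency(efficiency_percent)
    stopifnot(af > 1)
    slope <- -1 / log10(af)
  }
  structure(
    list(target = as.character(target), slope = slope,
         amplification_factor = af,
         efficiency_percent = primer_efficiency(af)),
    class = "primer_calibration"
  )
}

#' @export
print.primer_calibration <- function(x, ...) {
  cat(sprintf("Primer calibration [%s]: slope %.4f, AF %.4f, efficiency %.2f%%\n",
              x$target, x$slope, x$amplification_factor,
              x$efficiency_percent))
  invisible(x)
}

#' Printed primer calibrations for the engineered strains
#'
#' The standard-curve efficiencies determined for the reference
#' (chromosomal), plasmid and transposon targets: with a transposase, cmR
#' 100.91% (AF 2.01), kanR 103.47% (AF 2.03), tetA 98.97% (AF 1.99); without,
#' dxs 97.46% (AF 1.97), kanR 100.57% (AF 2.01), tetA 95.14% (AF 1.95).
#' These serve as the default calibrations of the synthetic-experiment
#' generator.
#'
#' @param strain `"with_transposase"` or `"without_transposase"`.
#' @return Named list of [primer_calibration()] objects
#'   (`reference`, `plasmid`, `transposon`).
#' @export
default_calibrations <- function(strain = c("with_transposase",
                                            "without_transposase")) {
  strain <- match.arg(strain)
  if (strain == "with_transposase") {
    list(
      reference  = primer_calibration("cmR", efficiency_percent = 100.91),
      plasmid    = primer_calibration("kanR", efficiency_percent = 103.47),
      transposon = primer_calibration("tetA", efficiency_percent = 98.97)
    )
  } else {
    list(
      reference  = primer_calibration("dxs", efficiency_percent = 97.46),
      plasmid    = primer_calibration("kanR", efficiency_percent = 100.57),
      transposon = primer_calibration("tetA", efficiency_percent = 95.14)
    )
  }
}

check_ct_af <- function(ct_ref, ct_target, af_ref, af_target) {
  vals <- c(ct_ref, ct_target, af_ref, af_target)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("Ct values and amplification factors must be finite", call. = FALSE)
  }
  if (any(c(af_ref, af_target) <= 1)) {
    stop("amplification factors must exceed 1", call. = FALSE)
  }
}

#' Relative plasmid copy number per genome
#'
#' `PCN = AF_ref^Ct_ref / AF_plasmid^Ct_plasmid`: the abundance of the
#' plasmid target relative to a single-copy chromosomal reference (cmR for
#' transposase strains, dxs otherwise), from the averaged Ct values and the
#' primer-specific amplification factors.
#'
#' @param ct_ref Ct of the chromosomal reference target.
#' @param ct_plasmid Ct of the plasmid target (e.g. kanR).
#' @param af_ref,af_plasmid Amplification factors, > 1.
#' @return Plasmid copies per genome.
#' @export
relative_pcn <- function(ct_ref, ct_plasmid, af_ref, af_plasmid) {
  check_ct_af(ct_ref, ct_plasmid, af_ref, af_plasmid)
  af_ref^ct_ref / af_plasmid^ct_plasmid
}

#' Relative transposon copy number per genome
#'
#' `TCN = AF_ref^Ct_ref / AF_tet^Ct_tet - chromosomal_copies`. Transposase
#' strains carry one transposon copy on the chromosome that never moves, so
#' that copy is subtracted (`chromosomal_copies = 1`, reference cmR);
#' transposase-free strains subtract nothing (`chromosomal_copies = 0`,
#' reference dxs). Measurement noise can push the corrected value slightly
#' below zero; it is returned as-is with a warning, never clipped, so the
#' noise stays visible downstream.
#'
#' @param ct_ref Ct of the chromosomal reference target.
#' @param ct_tet Ct of the transposon target (tetA).
#' @param af_ref,af_tet Amplification factors, > 1.
#' @param chromosomal_copies 0 or 1 transposon copies on the chromosome.
#' @return Transposon copies per genome (possibly slightly negative).
#' @export
relative_tcn <- function(ct_ref, ct_tet, af_ref, af_tet,
                         chromosomal_copies = 1L) {
  check_ct_af(ct_ref, ct_tet, af_ref, af_tet)
  if (!chromosomal_copies %in% c(0L, 1L)) {
    stop("'chromosomal_copies' must be 0 or 1", call. = FALSE)
  }
  out <- af_ref^ct_ref / af_tet^ct_tet - chromosomal_copies
  if (any(out < 0)) {
    warning("negative TCN after chromosomal-copy subtraction ",
            "(measurement noise); value reported as-is", call. = FALSE)
  }
  out
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of Ct against log10 dilution; the slope
#' gives the amplification factor and efficiency of the primer pair.
#'
#' @param dilution_log10 log10 of the template dilution for each reaction
#'   (at least 3 distinct values spanning >= 2 log10).
#' @param ct Measured Ct values, same length.
#' @param target Label stored in the returned calibration.
#' @return A [primer_calibration()] object.
#' @export
standard_curve_fit <- function(dilution_log10, ct, target = "target") {
  stopifnot(is.numeric(dilution_log10), is.numeric(ct),
            length(dilution_log10) == length(ct))
  ux <- unique(dilution_log10)
  if (length(dilution_log10) < 3L || length(ux) < 3L) {
    stop("need at least 3 dilution points with distinct dilutions",
         call. = FALSE)
  }
  if (diff(range(ux)) < 2) {
    stop("dilution series must span at least 2 log10 units", call. = FALSE)
  }
  fit <- stats::lm(ct ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("degenerate standard curve: fitted slope is not negative",
         call. = FALSE)
  }
  primer_calibration(target, slope = slope)
}

#' Quantify a tidy Ct table
#'
#' Averages technical replicates on the Ct scale (arithmetic mean) per
#' (replicate, day, target), then computes relative PCN and TCN per genome
#' for every (replicate, day).
#'
#' @param ct_table data.frame with columns `replicate`, `day`, `target`,
#'   `ct`.
#' @param calibrations Named list as returned by [default_calibrations()]
#'   (elements `reference`, `plasmid`, `transposon`).
#' @param chromosomal_copies Chromosomal transposon copies to subtract
#'   (1 for transposase strains, 0 otherwise).
#' @return data.frame with columns `replicate`, `day`, `pcn`, `tcn`.
#' @export
quantify_ct_table <- function(ct_table, calibrations,
                              chromosomal_copies = 1L) {
  stopifnot(is.data.frame(ct_table),
            all(c("replicate", "day", "target", "ct") %in% names(ct_table)))
  labs <- vapply(calibrations, function(x) x$target, character(1))
  afs <- vapply(calibrations, function(x) x$amplification_factor, numeric(1))
  agg <- stats::aggregate(ct ~ replicate + day + target, data = ct_table,
                          FUN = mean)
  key <- interaction(agg$replicate, agg$day, drop = TRUE)
  rows <- lapply(split(agg, key), function(df) {
    ct_of <- function(role) {
      v <- df$ct[df$target == labs[[role]]]
      if (length(v) != 1L) {
        stop(sprintf("replicate '%s' day %s: expected one Ct for target '%s'",
                     df$replicate[1], df$day[1], labs[[role]]), call. = FALSE)
      }
      v
    }
    pcn <- relative_pcn(ct_of("reference"), ct_of("plasmid"),
                        afs[["reference"]], afs[["plasmid"]])
    tcn <- suppressWarnings(
      relative_tcn(ct_of("reference"), ct_of("transposon"),
                   afs[["reference"]], afs[["transposon"]],
                   chromosomal_copies = chromosomal_copies))
    data.frame(replicate = df$replicate[1], day = df$day[1],
               pcn = pcn, tcn = tcn)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replicate, out$day), ]
  rownames(out) <- NULL
  out
}
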
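# Scalar turnover calculations: D2O-based fraction of newly synthesized
# fatty acids (with plasma-enrichment calibration from an external acetone-
# exchange standard curve), biomass fractional synthesis ratios, and
# internal-standard / protein-normalized abundances.

#' Calibrate D2O enrichment from an acetone-exchange standard curve
#'
#' Fits the ordinary least-squares line `signal ~ enrichment` on external
#' standards of known D2O enrichment; sample signals are converted to
#' enrichments by inverting the line.
#'
#' @param known_enrichment Known D2O enrichments of the standards (mole
#'   fraction or percent — units carry through to predictions).
#' @param signal Measured acetone-exchange signals of the standards.
#' @return An object of class `d2o_calibration` with `slope`, `intercept`,
#'   `r_squared`, `n_standards`.
#' @export
calibrate_d2o <- function(known_enrichment, signal) {
  if (length(known_enrichment) != length(signal)) {
    stop("known_enrichment and signal must have equal length")
  }
  if (length(known_enrichment) < 3L) {
    stop("at least 3 standards are required for a calibration curve")
  }
  if (stats::sd(known_enrichment) == 0 || stats::sd(signal) == 0) {
    stop("degenerate standards: zero variance in enrichment or signal")
  }
  fit <- stats::lm(signal ~ known_enrichment)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((signal - mean(signal))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n_standards = length(signal)
    ),
    class = "d2o_calibration"
  )
}

#' @export
print.d2o_calibration <- function(x, ...) {
  cat(sprintf(
    "<d2o_calibration> signal = %.6g * enrichment + %.6g (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_standards
  ))
  invisible(x)
}

#' Convert sample signals to D2O enrichment via a calibration curve
#'
#' @param calibration A [calibrate_d2o()] result.
#' @param signal Measured sample signals.
#' @return Estimated enrichments (inverse of the standard-curve line).
#' @export
predict_d2o_enrichment <- function(calibration, signal) {
  stopifnot(inherits(calibration, "d2o_calibration"))
  (signal - calibration$intercept) / calibration$slope
}

#' Fraction of newly synthesized fatty acid from D2O labeling
#'
#' A fatty acid synthesized at body-water deuterium enrichment `p` with `N`
#' exchangeable hydrogens reaches a plateau total labeled fraction of
#' `1 - (1 - p)^N`; the fraction of the pool newly synthesized during the
#' trace is the measured enrichment divided by that plateau. Values outside
#' `[0, 1]` are clamped and flagged.
#'
#' @param x Corrected MID (total labeled fraction is taken as `1 - M+0`) or,
#'   with `enrichment_is_scalar = TRUE`, a scalar enrichment. The
#'   M+1-only convention is available via `method = "m1"` on an MID.
#' @param p Body-water deuterium enrichment (mole fraction), `> 0`.
#' @param N Effective number of exchangeable hydrogens (default 22 for
#'   palmitate; must be set explicitly per fatty acid for anything else).
#' @param method `"total"` (default, 1 - M+0) or `"m1"` (M+1 fraction only).
#' @param enrichment_is_scalar Treat `x` as a precomputed enrichment.
#' @return Fraction newly synthesized in `[0, 1]`, with attribute
#'   `out_of_range` when clamping occurred.
#' @export
d2o_fraction_new <- function(x, p, N = 22, method = c("total", "m1"),
                             enrichment_is_scalar = FALSE) {
  method <- match.arg(method)
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("body-water enrichment p must lie in (0, 1]; p = 0 leaves the plateau undefined")
  }
  if (N <= 0) stop("N (exchangeable hydrogens) must be positive")
  e <- if (enrichment_is_scalar) {
    as.numeric(x)
  } else if (method == "total") {
    mid_enrichment(x)
  } else {
    assert_mid(x)
    if (length(x) < 2L) 0 else as.numeric(x)[2L]
  }
  plateau <- 1 - (1 - p)^N
  f <- e / plateau
  out_of_range <- f < 0 | f > 1
  f <- pmin(pmax(f, 0), 1)
  if (any(out_of_range)) attr(f, "out_of_range") <- out_of_range
  f
}

#' Biomass fractional synthesis
#'
#' Fraction of a macromolecule pool newly synthesized, computed as the total
#' enrichment of a monomer in the hydrolyzed biomass divided by the total
#' enrichment of the corresponding free (precursor) pool. A ratio above 1
#' (biomass more labeled than its precursor) is flagged, not silently
#' clamped.
#'
#' @param biomass_enrichment Total labeled fraction of the monomer in
#'   hydrolyzed biomass.
#' @param free_pool_enrichment Total labeled fraction of the free monomer
#'   pool (must be positive).
#' @return The ratio, with attribute `exceeds_one` when above 1.
#' @export
biomass_fractional_synthesis <- function(biomass_enrichment, free_pool_enrichment) {
  if (any(free_pool_enrichment <= 0)) {
    stop(
      "free pool enrichment must be positive: an unlabeled precursor pool ",
      "carries no information about biomass synthesis (check tracer choice and timing)"
    )
  }
  r <- biomass_enrichment / free_pool_enrichment
  if (any(r > 1)) {
    warning("biomass enrichment exceeds free-pool enrichment (ratio > 1); check pool assignments")
    attr(r, "exceeds_one") <- r > 1
  }
  r
}

#' Delta-method standard error of a biomass/free enrichment ratio
#'
#' First-order (delta-method) SE of `mean(biomass) / mean(free)` from
#' replicate enrichment measurements, assuming independent replicates.
#'
#' @param biomass_reps Replicate biomass-monomer enrichments.
#' @param free_reps Replicate free-pool enrichments.
#' @return Approximate standard error of the fractional-synthesis ratio.
#' @export
fractional_synthesis_se <- function(biomass_reps, free_reps) {
  b <- mean(biomass_reps)
  f <- mean(free_reps)
  if (f <= 0) stop("free pool enrichment must be positive")
  se_b <- stats::sd(biomass_reps) / sqrt(length(biomass_reps))
  se_f <- stats::sd(free_reps) / sqrt(length(free_reps))
  (b / f) * sqrt((se_b / b)^2 + (se_f / f)^2)
}

#' Internal-standard and protein-normalized abundance
#'
#' @param peak_area Analyte peak area.
#' @param internal_standard_area Internal standard (e.g. palmitate-d31) peak
#'   area, `> 0`.
#' @param protein_ug Protein content of the sample in micrograms, `> 0`.
#' @return Relative abundance per microgram protein.
#' @export
normalized_abundance <- function(peak_area, internal_standard_area, protein_ug) {
  if (any(internal_standard_area <= 0)) stop("internal standard area must be positive")
  if (any(protein_ug <= 0)) stop("protein amount must be positive")
  peak_area / internal_standard_area / protein_ug
}
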
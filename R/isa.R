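# Isotopomer spectral analysis (ISA) of fatty acid synthesis. A palmitate
# molecule is condensed from eight 2-carbon acetyl units; with a uniformly
# 13C-labeled glucose tracer each lipogenic unit is either fully labeled
# (M+2, probability D) or unlabeled. The measured palmitate pool is a
# mixture of pre-existing (unlabeled) molecules and molecules newly made
# during the trace (fraction g), so the corrected MID is
#   (1 - g) * delta(M+0) + g * Binomial(n_units, D) on even shifts.

#' Simulate the ISA palmitate MID
#'
#' @param D Fraction of lipogenic 2-carbon units carrying two tracer carbons,
#'   in `[0, 1]`.
#' @param g Fraction of the product pool newly synthesized during the trace,
#'   in `[0, 1]`.
#' @param n_units Number of condensed 2-carbon units (8 for palmitate).
#' @param unit_m1 Optional M+1 component of the acetyl unit (off by default:
#'   a uniformly labeled carbon tracer yields units that are fully labeled or
#'   unlabeled, and correction removes natural M+1).
#' @return An MID of length `2 * n_units + 1`.
#' @examples
#' isa_simulate(D = 0.5, g = 1)[1] # binomial(8, 0.5) mass at M+0
#' @export
isa_simulate <- function(D, g, n_units = 8L, unit_m1 = 0) {
  if (D < 0 || D > 1 || g < 0 || g > 1) stop("D and g must lie in [0, 1]")
  if (unit_m1 < 0 || D + unit_m1 > 1) stop("unit_m1 must be >= 0 with D + unit_m1 <= 1")
  n_units <- as.integer(n_units)
  if (n_units < 1L) stop("n_units must be >= 1")
  unit <- c(1 - D - unit_m1, unit_m1, D)
  synth <- mid_nfold_convolve(unit, n_units)
  mid_mixture(list(mid_delta(0), synth), c(1 - g, g))
}

# Unvalidated fast path used inside optimization loops; mirrors
# isa_simulate() but tolerates the tiny bound excursions of finite-difference
# gradients by clamping.
isa_simulate_raw <- function(D, g, n_units, unit_m1 = 0) {
  D <- min(max(D, 0), 1 - unit_m1)
  g <- min(max(g, 0), 1)
  unit <- c(1 - D - unit_m1, unit_m1, D)
  out <- 1
  for (i in seq_len(n_units)) out <- conv_raw(out, unit)
  out <- g * out
  out[1] <- out[1] + (1 - g)
  out
}

#' Pooled per-isotopologue measurement SD
#'
#' SD of each isotopologue across replicates, floored at `floor` mole
#' fraction. The floor is the community-standard MID error estimate and
#' prevents zero-weight blowup when replicates coincide.
#'
#' @param measured Matrix of replicate MIDs (rows = mass shifts, columns =
#'   replicates).
#' @param floor Minimum SD in mole-fraction units.
#' @return Numeric vector of per-isotopologue SDs.
#' @export
pooled_mid_sd <- function(measured, floor = 0.003) {
  measured <- as.matrix(measured)
  s <- if (ncol(measured) > 1L) apply(measured, 1, stats::sd) else numeric(nrow(measured))
  pmax(s, floor)
}

# Normalize replicate input (matrix or list of MIDs) to a shifts x replicates
# matrix, zero-padding shorter replicates.
replicate_matrix <- function(measured) {
  if (is.list(measured)) {
    len <- max(vapply(measured, length, integer(1)))
    measured <- vapply(measured, function(m) mid_pad(m, len), numeric(len))
  }
  m <- as.matrix(measured)
  for (j in seq_len(ncol(m))) {
    assert_mid(m[, j], tol = 1e-6, what = sprintf("replicate %d MID", j))
  }
  m
}

#' Fit the ISA model to replicate palmitate MIDs
#'
#' Minimizes the weighted sum of squared residuals
#' `sum_r sum_i ((sim_i - meas_ri) / sigma_i)^2` over `(D, g)` in the unit
#' square, fitting all replicates concurrently, from multiple
#' Latin-hypercube starts. 95% profile-likelihood confidence intervals are
#' computed by parameter continuation.
#'
#' @param measured Replicate MIDs: a matrix (rows = mass shifts, columns =
#'   replicates) or a list of MID vectors.
#' @param sigma Per-isotopologue SDs; defaults to [pooled_mid_sd()] of the
#'   replicates with `sigma_floor`.
#' @param n_units Number of 2-carbon units (8 for palmitate).
#' @param unit_m1 Optional acetyl-unit M+1 component, see [isa_simulate()].
#' @param sigma_floor Floor for the pooled SD.
#' @param n_starts Number of multistart points.
#' @param seed Seed for the (local) multistart stream.
#' @param compute_ci Compute profile-likelihood CIs for `D` and `g`.
#' @return A [fit_result] with parameters `D` and `g`.
#' @export
isa_fit <- function(measured, sigma = NULL, n_units = 8L, unit_m1 = 0,
                    sigma_floor = 0.003, n_starts = 20L, seed = 17L,
                    compute_ci = TRUE) {
  m <- replicate_matrix(measured)
  L <- 2L * as.integer(n_units) + 1L
  if (nrow(m) < L) m <- rbind(m, matrix(0, L - nrow(m), ncol(m)))
  if (is.null(sigma)) sigma <- pooled_mid_sd(m, floor = sigma_floor)
  if (any(sigma <= 0)) stop("all measurement SDs must be positive")
  sigma <- rep_len(sigma, nrow(m))
  resid_fn <- function(theta) {
    sim <- isa_simulate_raw(theta[1], theta[2], n_units, unit_m1)
    sim <- c(sim, numeric(nrow(m) - length(sim)))
    as.vector((sim - m) / sigma)
  }
  lower <- c(0, 0)
  upper <- c(1, 1)
  best <- fit_multistart(resid_fn, lower, upper, n_starts = n_starts, seed = seed)
  params <- stats::setNames(best$par, c("D", "g"))
  ci <- matrix(NA_real_, 2, 2, dimnames = list(c("D", "g"), c("lower", "upper")))
  fit <- fit_result(
    params = params, ssr = best$value, ci95 = ci,
    n_obs = length(m), converged = best$converged, n_starts = n_starts,
    resid_fn = resid_fn, lower = lower, upper = upper
  )
  if (compute_ci && best$converged) {
    fit$ci95["D", ] <- profile_ci(fit, "D")
    fit$ci95["g", ] <- profile_ci(fit, "g")
  }
  fit
}
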
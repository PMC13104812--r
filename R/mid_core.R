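# Core representation and algebra of mass isotopologue distributions (MIDs).
# An MID is a plain numeric vector of mole fractions indexed by integer mass
# shift: x[1] = M+0, x[2] = M+1, ... All downstream modules build on these
# operations, so the algebra here is deliberately strict: negative fractions
# are rejected, silent mass loss by truncation is an error.

#' Construct a mass isotopologue distribution (MID)
#'
#' An MID is a vector of mole fractions over integer mass shifts
#' M+0, M+1, ..., M+n. Fractions must be non-negative and sum to 1; raw
#' intensity vectors can be normalized on construction.
#'
#' @param fractions Numeric vector of mole fractions (or raw intensities if
#'   `normalize = TRUE`), ordered by mass shift starting at M+0.
#' @param analyte_id Optional analyte identifier stored as an attribute.
#' @param normalize If `TRUE`, divide by the sum (use for raw intensities).
#' @param tol Tolerance on `sum(fractions) == 1` when not normalizing.
#' @return A numeric vector of mole fractions summing to 1.
#' @examples
#' mid(c(0.25, 0.25, 0.5))
#' mid(c(1e5, 3e5), normalize = TRUE)
#' @export
mid <- function(fractions, analyte_id = NULL, normalize = FALSE, tol = 1e-8) {
  if (length(fractions) == 0L) {
    stop("an MID must contain at least the M+0 entry")
  }
  if (!is.numeric(fractions) || anyNA(fractions)) {
    stop("MID fractions must be numeric and non-missing")
  }
  x <- as.numeric(fractions)
  if (any(x < 0)) {
    stop("negative mole fractions are not allowed in an MID")
  }
  s <- sum(x)
  if (s <= 0) {
    stop("MID fractions sum to zero; nothing to normalize")
  }
  if (normalize) {
    x <- x / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf(
      "MID fractions must sum to 1 (got %.8g); use normalize = TRUE for raw intensities",
      s
    ))
  }
  if (!is.null(analyte_id)) attr(x, "analyte_id") <- analyte_id
  x
}

# Internal validity check used by the public algebra. Cheap on purpose.
assert_mid <- function(x, tol = 1e-6, what = "MID") {
  if (length(x) == 0L) stop(what, " is empty")
  if (!is.numeric(x) || anyNA(x)) stop(what, " must be numeric and non-missing")
  if (any(x < 0)) stop(what, " contains negative fractions")
  if (abs(sum(x) - 1) > tol) {
    stop(sprintf("%s does not sum to 1 (got %.8g)", what, sum(x)))
  }
  invisible(TRUE)
}

#' Point-mass MID at a given mass shift
#'
#' @param shift Integer mass shift carrying all the mass.
#' @param length_out Output length (defaults to `shift + 1`).
#' @return An MID with all mass at `M+shift`.
#' @export
mid_delta <- function(shift, length_out = shift + 1L) {
  shift <- as.integer(shift)
  if (shift < 0) stop("mass shift must be non-negative")
  if (length_out < shift + 1L) stop("length_out too short to hold the mass shift")
  x <- numeric(length_out)
  x[shift + 1L] <- 1
  x
}

#' Pad (or carefully truncate) an MID to a target length
#'
#' Padding appends zero fractions. Truncation is only permitted when the
#' dropped tail carries negligible mass; silently discarding mass would
#' corrupt mean-mass invariants downstream.
#'
#' @param x An MID.
#' @param length_out Target length.
#' @param tol Maximum tail mass that may be dropped on truncation.
#' @return An MID of length `length_out`.
#' @export
mid_pad <- function(x, length_out, tol = 1e-6) {
  n <- length(x)
  x <- as.numeric(x)
  if (length_out >= n) {
    return(c(x, numeric(length_out - n)))
  }
  dropped <- sum(x[(length_out + 1L):n])
  if (dropped > tol) {
    stop(sprintf(
      "truncating this MID to length %d would drop %.3g mole fraction (> %.1g)",
      length_out, dropped, tol
    ))
  }
  y <- x[seq_len(length_out)]
  y / sum(y)
}

# Direct (open) convolution of two small non-negative vectors. No FFT: the
# vectors here are short and exact non-negativity matters.
conv_raw <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  out <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    if (a[i] != 0) {
      idx <- i:(i + nb - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

#' Convolve two MIDs
#'
#' The MID of a molecule assembled from two independent moieties is the
#' convolution of the moiety MIDs: mass shifts add, probabilities multiply.
#'
#' @param a,b MIDs (non-negative, summing to 1).
#' @return An MID of length `length(a) + length(b) - 1`.
#' @examples
#' mid_convolve(c(0.5, 0.5), c(0.5, 0.5)) # c(0.25, 0.5, 0.25)
#' @export
mid_convolve <- function(a, b) {
  assert_mid(a, what = "first MID")
  assert_mid(b, what = "second MID")
  conv_raw(as.numeric(a), as.numeric(b))
}

#' n-fold self-convolution of a precursor-unit MID
#'
#' MID of a polymer built from `n` independent draws of the same precursor
#' unit (e.g. a fatty acid from n 2-carbon acetyl units). `n = 0` returns the
#' identity element, a point mass at M+0.
#'
#' @param u Precursor-unit MID.
#' @param n Non-negative integer number of units.
#' @return An MID of length `n * (length(u) - 1) + 1`.
#' @export
mid_nfold_convolve <- function(u, n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop("n must be a single non-negative integer")
  }
  assert_mid(u, what = "unit MID")
  n <- as.integer(n)
  out <- 1
  u <- as.numeric(u)
  for (i in seq_len(n)) out <- conv_raw(out, u)
  out
}

#' Convex mixture of MIDs
#'
#' Weighted sum of component MIDs (components are zero-padded to a common
#' length first). Used to mix pre-existing and newly synthesized pools.
#'
#' @param components List of MIDs.
#' @param weights Non-negative mole fractions summing to 1, one per component.
#' @return The mixture MID.
#' @export
mid_mixture <- function(components, weights) {
  if (!is.list(components) || length(components) == 0L) {
    stop("components must be a non-empty list of MIDs")
  }
  if (length(weights) != length(components)) {
    stop("weights and components length mismatch")
  }
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  for (k in seq_along(components)) assert_mid(components[[k]], what = sprintf("component %d", k))
  len <- max(vapply(components, length, integer(1)))
  out <- numeric(len)
  for (k in seq_along(components)) {
    out <- out + weights[k] * mid_pad(components[[k]], len)
  }
  out
}

#' Total fraction labeled (enrichment) of an MID
#'
#' @param x An MID.
#' @return `1 - x[M+0]`, the total labeled fraction, in `[0, 1]`.
#' @export
mid_enrichment <- function(x) {
  assert_mid(x)
  1 - as.numeric(x)[1L]
}

#' Mean mass shift of an MID
#'
#' @param x An MID.
#' @return The expected mass shift `sum(shift * fraction)`.
#' @export
mid_mean_shift <- function(x) {
  assert_mid(x)
  x <- as.numeric(x)
  sum((seq_along(x) - 1) * x)
}
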
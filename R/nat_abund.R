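# Natural isotope abundance correction. Measured mass spectra of derivatized
# metabolites are contaminated by naturally occurring heavy isotopes of every
# atom in the detected fragment (including derivatization C/H/Si). A
# correction matrix maps tracer-only MIDs to raw spectra; inverting it by
# nonnegativity-constrained least squares recovers the tracer-only MID.
# The same matrix, applied forward, is the "contamination" step of the
# synthetic-data generator.

#' Default natural isotope abundance table
#'
#' IUPAC representative isotopic compositions, expressed per element as mole
#' fractions over integer mass shifts relative to the lightest isotope.
#' Covers C, H, N, O, S, Si and P; override with [read_isotope_table()] for
#' custom values.
#'
#' @return A data.frame with columns `element`, `mass_shift`, `abundance`.
#' @export
isotope_table <- function() {
  data.frame(
    element = c(
      "C", "C",
      "H", "H",
      "N", "N",
      "O", "O", "O",
      "S", "S", "S", "S",
      "Si", "Si", "Si",
      "P"
    ),
    mass_shift = c(
      0L, 1L,
      0L, 1L,
      0L, 1L,
      0L, 1L, 2L,
      0L, 1L, 2L, 4L,
      0L, 1L, 2L,
      0L
    ),
    abundance = c(
      0.9893, 0.0107,
      0.999885, 0.000115,
      0.99636, 0.00364,
      0.99757, 0.00038, 0.00205,
      0.9499, 0.0075, 0.0425, 0.0001,
      0.92223, 0.04685, 0.03092,
      1.0
    ),
    stringsAsFactors = FALSE
  )
}

#' Read an isotope abundance table from file
#'
#' @param path CSV file with columns `element`, `mass_shift`, `abundance`.
#' @return A data.frame usable wherever [isotope_table()] is accepted.
#' @export
read_isotope_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "mass_shift", "abundance")
  if (!all(need %in% names(tbl))) {
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  }
  tbl
}

#' Parse a Hill-notation elemental formula
#'
#' @param formula String such as `"C17H34O2"` or `"C14H32NO2Si2"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(vapply(formula, as.integer, integer(1)))
  }
  if (!is.character(formula) || length(formula) != 1L) {
    stop("formula must be a single Hill-notation string or a named count vector")
  }
  s <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L || sum(nchar(parts)) != nchar(s)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Molecule specification for isotope correction
#'
#' Describes one analyte (the *detected* species, so derivatization atoms
#' belong in the formula, e.g. the TBDMS or FAME adduct) plus which element is
#' traced and how many of its atoms can carry tracer label.
#'
#' @param analyte_id Analyte identifier.
#' @param formula Hill-notation string or named element-count vector.
#' @param tracer_element Traced element (`"C"` for 13C, `"H"` for deuterium,
#'   `"N"` for 15N).
#' @param n_traceable Number of atoms of `tracer_element` that can carry label.
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(analyte_id, formula, tracer_element = "C", n_traceable) {
  counts <- parse_formula(formula)
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (!tracer_element %in% names(counts)) {
    # tracer element absent from the fragment: legal only with no traceable atoms
    counts <- c(counts, stats::setNames(0L, tracer_element))
  }
  n_traceable <- as.integer(n_traceable)
  if (n_traceable < 0 || n_traceable > counts[[tracer_element]]) {
    stop(sprintf(
      "n_traceable (%d) must lie in [0, %d] for %s",
      n_traceable, counts[[tracer_element]], analyte_id
    ))
  }
  structure(
    list(
      analyte_id = analyte_id,
      formula = counts,
      tracer_element = tracer_element,
      n_traceable = n_traceable
    ),
    class = "molecule_spec"
  )
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf(
    "<molecule_spec> %s: %s, tracer %s (%d traceable)\n",
    x$analyte_id,
    paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""), collapse = ""),
    x$tracer_element, x$n_traceable
  ))
  invisible(x)
}

# Per-atom natural-abundance distribution for one element, as a dense MID.
atom_dist <- function(element, table) {
  rows <- table[table$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown element in isotope table: ", element)
  d <- numeric(max(rows$mass_shift) + 1L)
  d[rows$mass_shift + 1L] <- rows$abundance
  d / sum(d)
}

#' Natural-abundance MID of n atoms of one element
#'
#' @param element Element symbol.
#' @param n Number of atoms.
#' @param table Isotope abundance table.
#' @return The n-fold convolution of the per-atom distribution.
#' @export
element_mid <- function(element, n, table = isotope_table()) {
  mid_nfold_convolve(atom_dist(element, table), n)
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (for `j = 0..n_traceable` forced-labeled tracer atoms) is the
#' natural-abundance spectrum of the remaining atoms — including the
#' *unlabeled* atoms of the tracer element — shifted up by `j`. The matrix
#' maps a tracer-only MID to the raw measured spectrum. Rows extend
#' `tail_shifts` beyond `n_traceable` to hold heavy-isotope tails (Si in
#' TBDMS fragments); any remaining tail mass is dropped and recorded.
#'
#' @param spec A [molecule_spec()].
#' @param table Isotope abundance table.
#' @param L_raw Number of raw spectrum rows; default `n_traceable + 1 + tail_shifts`.
#' @param tail_shifts Extra rows beyond `n_traceable` (default 4).
#' @return An object of class `correction_model` with elements `spec`,
#'   `matrix` (`L_raw x (n_traceable + 1)`), `isotope_table`, and
#'   `dropped_tail` (per-column truncated mass).
#' @export
build_correction_matrix <- function(spec, table = isotope_table(),
                                    L_raw = NULL, tail_shifts = 4L) {
  stopifnot(inherits(spec, "molecule_spec"))
  n_tr <- spec$n_traceable
  if (is.null(L_raw)) L_raw <- n_tr + 1L + as.integer(tail_shifts)
  L_raw <- as.integer(L_raw)
  if (L_raw < n_tr + 1L) {
    stop(sprintf("L_raw (%d) too small to hold %d tracer shifts", L_raw, n_tr))
  }
  counts <- spec$formula
  for (el in names(counts)) atom_dist(el, table) # fail early on unknown elements

  # Spectrum of all non-tracer atoms.
  non_tracer <- 1
  for (el in setdiff(names(counts), spec$tracer_element)) {
    if (counts[[el]] > 0L) non_tracer <- conv_raw(non_tracer, element_mid(el, counts[[el]], table))
  }
  tracer_atom <- atom_dist(spec$tracer_element, table)
  n_el <- counts[[spec$tracer_element]]

  # Powers of the tracer-element per-atom distribution, 0..n_el.
  pw <- vector("list", n_el + 1L)
  pw[[1]] <- 1
  for (k in seq_len(n_el)) pw[[k + 1L]] <- conv_raw(pw[[k]], tracer_atom)

  M <- matrix(0, nrow = L_raw, ncol = n_tr + 1L)
  dropped <- numeric(n_tr + 1L)
  for (j in 0:n_tr) {
    spec_j <- conv_raw(non_tracer, pw[[n_el - j + 1L]])
    col <- numeric(L_raw)
    idx <- seq_along(spec_j) + j
    keep <- idx <= L_raw
    col[idx[keep]] <- spec_j[keep]
    dropped[j + 1L] <- sum(spec_j[!keep])
    M[, j + 1L] <- col
  }
  structure(
    list(
      spec = spec,
      matrix = M,
      isotope_table = table,
      dropped_tail = dropped,
      truncated = any(dropped > 1e-3)
    ),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> %s: %d raw shifts x %d tracer states; max truncated tail %.3g\n",
    x$spec$analyte_id, nrow(x$matrix), ncol(x$matrix), max(x$dropped_tail)
  ))
  invisible(x)
}

#' Correct a raw spectrum for natural isotope abundance
#'
#' Solves `raw = matrix %*% corrected` for the tracer-only MID by least
#' squares under a non-negativity constraint, then renormalizes. Plain matrix
#' inversion yields negative fractions at low enrichment; the constrained
#' solve confines that cleanup to this one place.
#'
#' @param raw Raw measured spectrum (fractions, or intensities with
#'   `normalize = TRUE`).
#' @param model A [build_correction_matrix()] result.
#' @param normalize Normalize `raw` before solving.
#' @param cond_threshold Condition number above which a warning is issued.
#' @return Corrected MID of length `n_traceable + 1`, with attributes
#'   `residual_norm` (Euclidean norm of the least-squares residual) and
#'   `ill_conditioned`.
#' @export
correct_mid <- function(raw, model, normalize = TRUE, cond_threshold = 1e8) {
  stopifnot(inherits(model, "correction_model"))
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("raw spectrum has negative entries")
  if (normalize) raw <- raw / sum(raw) else assert_mid(raw, what = "raw spectrum")
  L <- nrow(model$matrix)
  raw <- mid_pad(raw, L, tol = 1e-3)
  kap <- kappa(model$matrix, exact = FALSE)
  flagged <- is.finite(kap) && kap > cond_threshold
  if (flagged) {
    warning(sprintf(
      "correction matrix for %s is ill-conditioned (condition number %.3g)",
      model$spec$analyte_id, kap
    ))
  }
  sol <- pracma::lsqnonneg(model$matrix, raw)
  x <- pmax(sol$x, 0)
  if (sum(x) <= 0) stop("correction produced an all-zero MID")
  resid <- sqrt(sum((model$matrix %*% x - raw)^2))
  x <- x / sum(x)
  attr(x, "residual_norm") <- resid
  attr(x, "ill_conditioned") <- flagged
  x
}

#' Contaminate a tracer-only MID with natural abundance
#'
#' Forward model: `matrix %*% corrected`, renormalized. This is the inverse
#' of [correct_mid()] up to tail truncation and is what the synthetic-data
#' generator applies before emitting "raw" spectra.
#'
#' @param corrected Tracer-only MID of length at most `n_traceable + 1`.
#' @param model A [build_correction_matrix()] result.
#' @return Raw spectrum of length `L_raw`.
#' @export
contaminate <- function(corrected, model) {
  stopifnot(inherits(model, "correction_model"))
  assert_mid(corrected, what = "corrected MID")
  n_states <- ncol(model$matrix)
  if (length(corrected) > n_states) {
    corrected <- mid_pad(corrected, n_states) # errors if real mass would be lost
  } else {
    corrected <- mid_pad(corrected, n_states)
  }
  y <- as.numeric(model$matrix %*% corrected)
  y / sum(y)
}

#' Built-in metabolite dictionary
#'
#' Detected-fragment formulas (analyte plus derivatization atoms) with tracer
#' element and traceable atom counts for the analytes used throughout the
#' package and its synthetic datasets. GC-MS entries use standard TBDMS /
#' FAME fragment chemistry and LC-MS entries use intact lipid formulas; these
#' are reconstructions of typical fragments, not vendor-verified assignments,
#' and can be replaced via [read_metabolite_dictionary()].
#'
#' @return A data.frame with columns `analyte_id`, `formula`,
#'   `tracer_element`, `n_traceable`.
#' @export
default_dictionary <- function() {
  data.frame(
    analyte_id = c(
      "palmitate",        # palmitate FAME
      "palmitate_g0",     # same fragment, boundary-case analyte
      "palmitate_d2o",    # palmitate FAME, deuterium tracing
      "alanine",          # Ala 2TBDMS [M-57]
      "aspartate",        # Asp 3TBDMS [M-57]
      "aspartate_biomass",
      "serine",           # Ser 3TBDMS [M-57]
      "glyc3p",           # glycerol 3-phosphate (underivatized mass)
      "Glyc3P",
      "acyl16",
      "DHCer", "Cer", "LacCer", "GM3", "Gb4", "GM3_boundary",
      "LPC16", "LPC24", "SM34", "SM42", "SM34_boundary"
    ),
    formula = c(
      "C17H34O2",
      "C17H34O2",
      "C17H34O2",
      "C14H32NO2Si2",
      "C18H40NO4Si3",
      "C18H40NO4Si3",
      "C17H40NO3Si3",
      "C3H9O6P",
      "C3H9O6P",
      "C16H32O2",
      "C34H69NO3", "C34H67NO3", "C46H87NO13", "C57H104N2O21", "C60H112N2O23",
      "C57H104N2O21",
      "C24H50NO7P", "C32H66NO7P", "C39H79N2O6P", "C47H95N2O6P", "C39H79N2O6P"
    ),
    tracer_element = c(
      "C", "C", "H", "C", "C", "C", "C", "C", "C", "C",
      "C", "C", "C", "C", "C", "C",
      "C", "C", "C", "C", "C"
    ),
    n_traceable = c(
      16L, 16L, 22L, 3L, 4L, 4L, 3L, 3L, 3L, 16L,
      34L, 34L, 46L, 57L, 60L, 57L,
      24L, 32L, 39L, 47L, 39L
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a metabolite dictionary CSV
#'
#' @param path CSV with columns `analyte_id`, `formula` (Hill notation),
#'   `tracer_element`, `n_traceable`.
#' @return A data.frame in the same layout as [default_dictionary()].
#' @export
read_metabolite_dictionary <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte_id", "formula", "tracer_element", "n_traceable")
  if (!all(need %in% names(tbl))) {
    stop("metabolite dictionary must have columns: ", paste(need, collapse = ", "))
  }
  tbl
}

#' Build molecule specs from a dictionary table
#'
#' @param dictionary A data.frame as from [default_dictionary()].
#' @return Named list of [molecule_spec()] objects keyed by `analyte_id`.
#' @export
dictionary_specs <- function(dictionary = default_dictionary()) {
  specs <- lapply(seq_len(nrow(dictionary)), function(i) {
    molecule_spec(
      dictionary$analyte_id[i],
      dictionary$formula[i],
      dictionary$tracer_element[i],
      dictionary$n_traceable[i]
    )
  })
  names(specs) <- dictionary$analyte_id
  specs
}
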
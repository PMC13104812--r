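# Shared fixtures for the test suite. All synthetic inputs are built in code.

# A random valid MID of given length under the current RNG state.
random_mid <- function(len) {
  x <- stats::runif(len)
  x / sum(x)
}

# Brute-force natural-abundance spectrum by enumerating every isotope
# assignment of every atom (independent of the convolution implementation).
# Feasible for molecules with few atoms only.
enumerate_spectrum <- function(counts, table) {
  atoms <- list()
  for (el in names(counts)) {
    rows <- table[table$element == el, , drop = FALSE]
    d <- rows$abundance / sum(rows$abundance)
    names(d) <- rows$mass_shift
    atoms <- c(atoms, rep(list(d), counts[[el]]))
  }
  if (length(atoms) == 0L) return(1)
  grids <- expand.grid(lapply(atoms, function(d) seq_along(d)))
  n_shift_max <- sum(vapply(atoms, function(d) max(as.integer(names(d))), numeric(1)))
  out <- numeric(n_shift_max + 1L)
  for (i in seq_len(nrow(grids))) {
    p <- 1
    shift <- 0L
    for (a in seq_along(atoms)) {
      k <- grids[i, a]
      p <- p * atoms[[a]][k]
      shift <- shift + as.integer(names(atoms[[a]])[k])
    }
    out[shift + 1L] <- out[shift + 1L] + p
  }
  out
}

# Brute-force correction column: j tracer atoms forced labeled, the rest of
# the molecule at natural abundance, shifted by j.
enumerate_correction_column <- function(spec, j, table, L_raw) {
  counts <- spec$formula
  counts[[spec$tracer_element]] <- counts[[spec$tracer_element]] - j
  sp <- enumerate_spectrum(counts[counts > 0], table)
  col <- numeric(L_raw)
  idx <- seq_along(sp) + j
  keep <- idx <= L_raw
  col[idx[keep]] <- sp[keep]
  col
}

# Pure-light isotope table (every element monoisotopic); turns correction
# matrices into identities.
pure_isotope_table <- function(elements = c("C", "H", "N", "O")) {
  data.frame(
    element = elements, mass_shift = 0L, abundance = 1,
    stringsAsFactors = FALSE
  )
}

# Measurements + fixed inputs for the GSL preset from a generated dataset.
gsl_fit_inputs <- function(ds) {
  corr <- ds$corrected_mids
  meas <- lapply(c("LacCer", "GM3", "Gb4"), function(a) mid_matrix(corr, a))
  names(meas) <- c("LacCer", "GM3", "Gb4")
  fixed <- list(
    Cer_data = rowMeans(mid_matrix(corr, "Cer")),
    LacCer_data = rowMeans(mid_matrix(corr, "LacCer"))
  )
  list(measurements = meas, fixed_inputs = fixed)
}

gsl_truth_params <- function(truth) {
  p <- unlist(truth[c("g_LacCer", "g_GM3", "g_Gb4", "h", "s9", "s11", "hn6", "hn8")])
  names(p) <- c("g_LacCer", "g_GM3", "g_Gb4", "h", "s9", "s11", "hn6", "hn8")
  p
}
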
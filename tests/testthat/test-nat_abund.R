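test_that("Hill-notation formulas parse to element counts", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("C14H32NO2Si2"), c(C = 14L, H = 32L, N = 1L, O = 2L, Si = 2L))
  expect_equal(parse_formula("CHN"), c(C = 1L, H = 1L, N = 1L))
  expect_error(parse_formula("c6h12"), "parse")
})

test_that("molecule specs validate traceable-atom counts", {
  expect_error(molecule_spec("x", "C2H4", "C", 3), "n_traceable")
  sp <- molecule_spec("x", "H2", "C", 0) # tracer element absent, zero traceable
  expect_equal(sp$n_traceable, 0L)
  expect_error(molecule_spec("x", "H2", "C", 1), "n_traceable")
})

test_that("correction columns match single-molecule closed forms", {
  tab <- isotope_table()
  a <- tab$abundance[tab$element == "C" & tab$mass_shift == 1]
  # C2 tracer fragment: column 0 enumerates both atoms' isotope states
  m <- build_correction_matrix(molecule_spec("c2", "C2", "C", 2), tab)
  expect_equal(m$matrix[1:3, 1], c((1 - a)^2, 2 * a * (1 - a), a^2), tolerance = 1e-12)
  # fully labeled column is a shifted single-atom spectrum
  expect_equal(m$matrix[3, 3], 1)
  # H2 fragment with a carbon tracer: single column, binomial over 2H abundance
  h <- tab$abundance[tab$element == "H" & tab$mass_shift == 1]
  mh <- build_correction_matrix(molecule_spec("h2", "H2", "C", 0), tab, L_raw = 3)
  expect_equal(ncol(mh$matrix), 1L)
  expect_equal(mh$matrix[, 1], dbinom(0:2, 2, h), tolerance = 1e-12)
})

test_that("a monoisotopic element table yields an identity correction", {
  tab <- pure_isotope_table()
  m <- build_correction_matrix(molecule_spec("x", "C3", "C", 3), tab, L_raw = 4)
  expect_equal(m$matrix, diag(4))
  raw <- c(0.2, 0.3, 0.4, 0.1)
  expect_equal(as.numeric(correct_mid(raw, m)), raw, tolerance = 1e-10)
})

test_that("correction matrices agree with brute-force isotope enumeration", {
  tab <- isotope_table()
  panel <- list(
    molecule_spec("c2o", "C2O", "C", 2),
    molecule_spec("c2h2n", "C2H2N", "C", 2),
    molecule_spec("chnos", "CHNOS", "C", 1),
    molecule_spec("h2si", "H2Si", "H", 2)
  )
  for (sp in panel) {
    L <- sp$n_traceable + 5L
    m <- build_correction_matrix(sp, tab, L_raw = L)
    for (j in 0:sp$n_traceable) {
      expect_equal(
        m$matrix[, j + 1],
        enumerate_correction_column(sp, j, tab, L),
        tolerance = 1e-12
      )
    }
  }
})

test_that("contaminate and correct are mutual inverses", {
  specs <- dictionary_specs()
  for (id in c("palmitate", "alanine", "glyc3p")) {
    model <- build_correction_matrix(specs[[id]])
    n <- specs[[id]]$n_traceable + 1L
    withr::with_seed(11, {
      for (i in 1:20) {
        x <- random_mid(n)
        back <- correct_mid(contaminate(x, model), model)
        expect_equal(as.numeric(back), x, tolerance = 1e-8)
      }
    })
    # unlabeled standard: column 0 corrects to a pure M+0 pool
    std <- model$matrix[, 1] / sum(model$matrix[, 1])
    expect_equal(as.numeric(correct_mid(std, model)), mid_delta(0, n), tolerance = 1e-8)
    # fully labeled pool maps onto the last column
    expect_equal(
      contaminate(mid_delta(specs[[id]]$n_traceable), model),
      model$matrix[, n] / sum(model$matrix[, n]),
      tolerance = 1e-12
    )
  }
})

test_that("correction reports residuals and never returns negative fractions", {
  model <- build_correction_matrix(dictionary_specs()[["alanine"]])
  raw <- contaminate(c(0.7, 0.1, 0.1, 0.1), model)
  out <- correct_mid(raw, model)
  expect_true(all(out >= 0))
  expect_lt(attr(out, "residual_norm"), 1e-10)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # spectrum length never grows: corrected support is n_traceable + 1
  expect_lt(length(out), length(raw) + 1L)
})

test_that("matrix construction rejects unknown elements and short spectra", {
  expect_error(
    build_correction_matrix(molecule_spec("x", "C2Xe2", "C", 2)),
    "unknown element"
  )
  expect_error(
    build_correction_matrix(molecule_spec("x", "C4", "C", 4), L_raw = 3),
    "too small"
  )
})
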
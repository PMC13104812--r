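gsl_params <- c(
  g_LacCer = 1, g_GM3 = 1, g_Gb4 = 1,
  h = 0.9, s9 = 0.7, s11 = 0.1, hn6 = 0.5, hn8 = 0.2
)
unlabeled_fixed <- list(Cer_data = mid_delta(0), LacCer_data = mid_delta(0))

test_that("LacCer headgroup labeling follows the two-hexose-draw enumeration", {
  net <- gsl_network()
  for (h in c(0.3, 0.9)) {
    pars <- gsl_params
    pars["h"] <- h
    out <- species_synth_mid("LacCer", net, pars, unlabeled_fixed)
    expect_equal(out[7], 2 * h * (1 - h), tolerance = 1e-12) # M+6: one labeled hexose
    expect_equal(out[13], h^2, tolerance = 1e-12) # M+12: both labeled
    expect_equal(out[1], (1 - h)^2, tolerance = 1e-12)
    expect_equal(sum(out), 1, tolerance = 1e-10)
    # label sits only at the hexose shift combinations
    expect_equal(sum(out[-c(1, 7, 13)]), 0)
  }
})

test_that("a glycerolipid backbone from fully labeled Glyc3P lands at M+3", {
  net <- elongation_network()
  pars <- c(
    g_acyl24 = 0, g_LPC16 = 1, g_LPC24 = 0, g_SM34 = 0, g_SM42 = 0,
    a3 = 1, D = 0, e2 = 0
  )
  out <- species_synth_mid("LPC16", net, pars, list(acyl16_data = mid_delta(0)))
  expect_equal(which(out > 1e-12) - 1L, 3L)
  expect_equal(out[4], 1, tolerance = 1e-12)
})

test_that("fully unlabeled pools leave every species at M+0 regardless of g", {
  net <- gsl_network()
  pars <- gsl_params
  pars[c("h", "s9", "s11", "hn6", "hn8")] <- 0
  pars[c("g_LacCer", "g_GM3", "g_Gb4")] <- c(0.3, 0.8, 0.5)
  for (sp in c("LacCer", "GM3", "Gb4")) {
    out <- species_synth_mid(sp, net, pars, unlabeled_fixed)
    expect_equal(mid_enrichment(mid(out, normalize = TRUE)), 0, tolerance = 1e-12)
  }
})

test_that("simulated species MIDs sum to 1 and respect the mass ceiling", {
  net <- gsl_network()
  withr::with_seed(5, {
    for (i in 1:10) {
      pars <- gsl_params
      pars[] <- runif(length(pars))
      if (pars["s9"] + pars["s11"] > 1) pars[c("s9", "s11")] <- pars[c("s9", "s11")] / 2
      if (pars["hn6"] + pars["hn8"] > 1) pars[c("hn6", "hn8")] <- pars[c("hn6", "hn8")] / 2
      cer <- random_mid(3)
      fixed <- list(Cer_data = cer, LacCer_data = mid_pad(cer, 15))
      for (sp in c("LacCer", "GM3", "Gb4")) {
        out <- species_synth_mid(sp, net, pars, fixed)
        expect_equal(sum(out), 1, tolerance = 1e-9)
        expect_true(all(out >= -1e-15))
      }
      # GM3 ceiling: ceramide carbons + 2 hexoses + sialic acid
      expect_lte(length(species_synth_mid("GM3", net, pars, fixed)) - 1L, 2 + 6 + 6 + 11)
    }
  })
})

test_that("GM3 headgroup-only support matches the hexose/sialic shift lattice", {
  net <- gsl_network()
  pars <- gsl_params
  pars["g_LacCer"] <- 0.5
  lac <- species_synth_mid("LacCer", net, pars, unlabeled_fixed)
  fixed <- list(Cer_data = mid_delta(0), LacCer_data = lac)
  gm3 <- species_synth_mid("GM3", net, pars, fixed)
  support <- which(gm3 > 1e-12) - 1L
  lattice <- sort(unique(as.vector(outer(c(0, 6, 12), c(0, 9, 11), "+"))))
  expect_true(all(support %in% lattice))
  expect_setequal(support, c(0, 6, 9, 11, 12, 15, 17, 21, 23))
  # M+21 / M+23 appear exactly when the sialic pool carries M+9 / M+11 mass
  expect_gt(gm3[22], 0)
  expect_gt(gm3[24], 0)
  pars0 <- pars
  pars0[c("s9", "s11")] <- 0
  gm3_0 <- species_synth_mid("GM3", net, pars0, fixed)
  expect_equal(sum(gm3_0[c(22, 24)]), 0)
})

test_that("elongation stacks acetyl units onto the base chain", {
  expect_equal(elongation_mid(mid_delta(0), 4, mid_delta(2)), mid_delta(8))
  # an odd-shift backbone plus one labeled cycle produces odd products (M+5)
  out <- elongation_mid(mid_delta(3), 1, c(0.5, 0, 0.5))
  expect_equal(which(out > 0) - 1L, c(3L, 5L))
  # four cycles at D = 0.5 on an unlabeled chain follow binomial(4, 0.5)
  out4 <- elongation_mid(mid_delta(0), 4, c(0.5, 0, 0.5))
  expect_equal(out4[seq(1, 9, 2)], dbinom(0:4, 4, 0.5), tolerance = 1e-12)
  expect_error(elongation_mid(mid_delta(0), -1, c(0.5, 0, 0.5)), "non-negative")
})

test_that("network definitions reject cycles and unresolved moieties", {
  expect_error(
    lipid_network(
      species = list(
        lipid_species("A", "B"),
        lipid_species("B", "A")
      ),
      pools = list()
    ),
    "cyclic"
  )
  expect_error(
    lipid_network(
      species = list(lipid_species("A", "nowhere")),
      pools = list()
    ),
    "unresolved"
  )
})

test_that("noiseless self-simulated GSL data are recovered exactly", {
  ds <- generate_synth("gsl_network", seed = 3, noise_sd = 0)
  inputs <- gsl_fit_inputs(ds)
  fit <- network_fit(gsl_network(), inputs$measurements, inputs$fixed_inputs,
    compute_ci = FALSE
  )
  truth <- gsl_truth_params(ds$truth)
  expect_true(fit$converged)
  expect_equal(fit$params[names(truth)], truth, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-10)
})

test_that("GM3 identical to LacCer forces zero sialic-acid labeling", {
  ds <- generate_synth("gsl_network", seed = 4, noise_sd = 0)
  inputs <- gsl_fit_inputs(ds)
  lac <- inputs$fixed_inputs$LacCer_data
  # GM3 measured as LacCer with an unlabeled sialic unit appended
  inputs$measurements$GM3 <- cbind(lac, lac, lac)
  fit <- network_fit(gsl_network(), inputs$measurements, inputs$fixed_inputs,
    compute_ci = FALSE
  )
  expect_lt(unname(fit$params["s9"] * fit$params["g_GM3"]), 1e-4)
  expect_lt(unname(fit$params["s11"] * fit$params["g_GM3"]), 1e-4)
})

test_that("dropping a species' data widens the CIs of parameters it informs", {
  ds <- generate_synth("gsl_network", seed = 6)
  inputs <- gsl_fit_inputs(ds)
  net <- gsl_network()
  full <- network_fit(net, inputs$measurements, inputs$fixed_inputs,
    ci_params = "h"
  )
  # without the LacCer measurement, h is informed only through Gb4
  net2 <- net
  net2$species$LacCer$measured <- FALSE
  reduced <- network_fit(net2, inputs$measurements[c("GM3", "Gb4")],
    inputs$fixed_inputs,
    ci_params = "h"
  )
  expect_gte(
    diff(reduced$ci95["h", ]) + 1e-6,
    diff(full$ci95["h", ])
  )
})

test_that("a boundary species with no synthesis flags its pool parameters", {
  ds <- generate_synth("gsl_network", seed = 8, noise_sd = 0)
  corr <- ds$corrected_mids
  inputs <- gsl_fit_inputs(ds)
  # replace GM3 data with the zero-synthesis boundary analyte
  inputs$measurements$GM3 <- mid_matrix(corr, "GM3_boundary")
  fit <- network_fit(gsl_network(), inputs$measurements, inputs$fixed_inputs,
    ci_params = c("g_GM3", "s9")
  )
  expect_lt(unname(fit$params["g_GM3"]), 1e-4)
  # the sialic enrichment is structurally unidentifiable and flagged
  expect_false(fit$identifiable[["s9"]])
})

test_that("moiety deconvolution recovers exact and noisy mixture weights", {
  basis <- list(un = mid_delta(0, 15), ribose = mid_delta(5, 15),
                base = mid_delta(9, 15), both = mid_delta(14, 15))
  w <- moiety_deconvolve(
    mid_mixture(basis[c("un", "ribose")], c(0.4, 0.6)),
    basis
  )
  expect_equal(as.numeric(w), c(0.4, 0.6, 0, 0), tolerance = 1e-10)
  expect_equal(as.numeric(moiety_deconvolve(basis[[3]], basis)), c(0, 0, 1, 0),
    tolerance = 1e-10
  )
  # noisy mixtures: weights recovered within 0.02 on average
  truth_w <- c(0.5, 0.3, 0.15, 0.05)
  withr::with_seed(21, {
    est <- replicate(100, {
      noisy <- pmax(mid_mixture(basis, truth_w) + rnorm(15, 0, 0.003), 0)
      as.numeric(moiety_deconvolve(noisy / sum(noisy), basis))
    })
    expect_lt(max(abs(rowMeans(est) - truth_w)), 0.02)
  })
  # duplicated component: rank deficiency is reported
  expect_warning(
    moiety_deconvolve(basis[[1]], list(basis[[1]], basis[[1]])),
    "rank"
  )
})
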
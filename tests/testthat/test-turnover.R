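test_that("the acetone-exchange calibration recovers a perfect line and inverts", {
  known <- c(0, 0.02, 0.04, 0.06, 0.08)
  signal <- 5 + 120 * known
  cal <- calibrate_d2o(known, signal)
  expect_equal(cal$slope, 120)
  expect_equal(cal$intercept, 5)
  expect_equal(cal$r_squared, 1)
  # a sample at a standard's signal maps back to that standard's enrichment
  expect_equal(predict_d2o_enrichment(cal, signal[3]), known[3], tolerance = 1e-12)
  expect_error(calibrate_d2o(c(0, 0.1), c(1, 2)), "at least 3")
  expect_error(calibrate_d2o(rep(0.1, 4), 1:4), "degenerate")
})

test_that("noisy calibrations estimate the slope within sampling error", {
  known <- seq(0, 0.08, length.out = 6)
  sd_noise <- 0.5
  withr::with_seed(33, {
    slopes <- replicate(100, {
      calibrate_d2o(known, 5 + 120 * known + rnorm(6, 0, sd_noise))$slope
    })
  })
  # analytic SE of an OLS slope with known noise SD
  se <- sd_noise / sqrt(sum((known - mean(known))^2))
  expect_lt(abs(mean(slopes) - 120), 3 * se / sqrt(100))
})

test_that("the D2O fraction-new formula scales enrichment by the plateau", {
  expect_equal(d2o_fraction_new(mid_delta(0), p = 0.02), 0)
  # plateau saturation: a fully renewed pool returns exactly 1
  p <- 0.02
  N <- 22
  plateau <- 1 - (1 - p)^N
  expect_equal(
    d2o_fraction_new(plateau, p = p, N = N, enrichment_is_scalar = TRUE), 1
  )
  # direct evaluation of the published working example scale
  f <- d2o_fraction_new(0.1789, p = 0.02, N = 22, enrichment_is_scalar = TRUE)
  expect_equal(f, 0.1789 / plateau, tolerance = 1e-12)
  expect_equal(f, 0.50, tolerance = 0.01)
  expect_error(d2o_fraction_new(0.1, p = 0, enrichment_is_scalar = TRUE), "p = 0")
  over <- d2o_fraction_new(plateau * 1.2, p = p, N = N, enrichment_is_scalar = TRUE)
  expect_equal(as.numeric(over), 1)
  expect_true(attr(over, "out_of_range"))
})

test_that("fraction-new is monotone in enrichment and antitone in p", {
  es <- seq(0, 0.2, by = 0.02)
  f_e <- vapply(es, d2o_fraction_new, numeric(1),
    p = 0.045, N = 22, enrichment_is_scalar = TRUE
  )
  expect_true(all(diff(f_e) > 0))
  ps <- seq(0.01, 0.10, by = 0.01)
  f_p <- vapply(ps, function(p) {
    d2o_fraction_new(0.05, p = p, N = 22, enrichment_is_scalar = TRUE)
  }, numeric(1))
  expect_true(all(diff(f_p) < 0))
})

test_that("biomass fractional synthesis is a guarded, scale-invariant ratio", {
  expect_equal(biomass_fractional_synthesis(0.03, 0.30), 0.10)
  expect_equal(biomass_fractional_synthesis(0.25, 0.25), 1.0)
  # scale invariance: percent vs fraction units give the same ratio
  expect_equal(
    biomass_fractional_synthesis(3, 30),
    biomass_fractional_synthesis(0.03, 0.30)
  )
  expect_error(biomass_fractional_synthesis(0.1, 0), "positive")
  expect_warning(r <- biomass_fractional_synthesis(0.4, 0.3), "exceeds")
  expect_true(attr(r, "exceeds_one"))
})

test_that("delta-method ratio precision matches the bootstrap", {
  withr::with_seed(55, {
    ratios <- se_delta <- numeric(100)
    for (i in 1:100) {
      b <- rnorm(3, 0.03, 0.003)
      f <- rnorm(3, 0.30, 0.01)
      se_delta[i] <- fractional_synthesis_se(b, f)
      ratios[i] <- mean(b) / mean(f)
    }
    # bootstrap-free oracle: the empirical SD of the ratio across simulations
    expect_lt(abs(mean(se_delta) - sd(ratios)) / sd(ratios), 0.10)
  })
})

test_that("normalized abundances follow the internal-standard convention", {
  expect_equal(normalized_abundance(100, 100, 1), 1)
  expect_equal(
    normalized_abundance(100, 50, 2),
    normalized_abundance(100, 50, 1) / 2
  )
  expect_error(normalized_abundance(1, 0, 1), "positive")
  expect_error(normalized_abundance(1, 1, 0), "positive")
})
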
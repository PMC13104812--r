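test_that("the ISA forward model reproduces its boundary and closed-form cases", {
  expect_equal(isa_simulate(D = 0.7, g = 0), mid_delta(0, 17))
  expect_equal(isa_simulate(D = 1, g = 1), mid_delta(16, 17))
  sim <- isa_simulate(D = 0.5, g = 1)
  expect_equal(sim[1], 0.00390625) # binomial(8, 0.5) at M+0
  expect_equal(sim[seq(1, 17, 2)], dbinom(0:8, 8, 0.5), tolerance = 1e-12)
  expect_equal(sim[seq(2, 16, 2)], rep(0, 8)) # no mass at odd shifts
  expect_equal(sum(sim), 1, tolerance = 1e-12)
  expect_equal(mid_mean_shift(isa_simulate(0.3, 0.6)), 0.6 * 8 * 2 * 0.3, tolerance = 1e-12)
  expect_error(isa_simulate(D = 1.2, g = 0.5), "\\[0, 1\\]")
})

test_that("noiseless replicate data are recovered exactly with near-zero objective", {
  truth <- isa_simulate(D = 0.6, g = 0.3)
  fit <- isa_fit(cbind(truth, truth, truth), compute_ci = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["D"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(fit$params["g"]), 0.3, tolerance = 1e-6)
  expect_lt(fit$objective(c(0.6, 0.3)), 1e-12)
  expect_lt(fit$ssr, 1e-12)
})

test_that("an unlabeled pool pins g at zero and leaves D unidentifiable", {
  m <- cbind(mid_delta(0, 17), mid_delta(0, 17), mid_delta(0, 17))
  fit <- isa_fit(m)
  expect_lt(unname(fit$params["g"]), 1e-6)
  # with no synthesis, the unit enrichment is unconstrained: CI spans [0, 1]
  expect_equal(unname(fit$ci95["D", ]), c(0, 1), tolerance = 1e-3)
  # clamping rule at the boundary: lower end of g sits at 0
  expect_equal(unname(fit$ci95["g", 1]), 0)
})

test_that("profile CIs shrink as the measurement SD floor shrinks", {
  truth <- isa_simulate(D = 0.5, g = 0.25)
  m <- cbind(truth, truth, truth)
  wide <- isa_fit(m, sigma_floor = 0.003)
  narrow <- isa_fit(m, sigma_floor = 3e-4)
  for (p in c("D", "g")) {
    w1 <- diff(wide$ci95[p, ])
    w2 <- diff(narrow$ci95[p, ])
    expect_lt(w2, w1 / 5)
  }
})

test_that("continuation CIs agree with a dense grid-search profile", {
  withr::with_seed(101, {
    for (i in 1:5) {
      D0 <- runif(1, 0.2, 0.8)
      g0 <- runif(1, 0.1, 0.6)
      m <- sapply(1:3, function(r) {
        y <- pmax(isa_simulate(D0, g0) + rnorm(17, 0, 0.003), 0)
        y / sum(y)
      })
      fit <- isa_fit(m)
      target <- fit$ssr + qchisq(0.95, 1)
      grid_step <- 0.005
      for (p in c("D", "g")) {
        idx <- match(p, names(fit$params))
        # independent oracle: profile the SSR on a dense grid, optimizing the
        # other parameter by one-dimensional search at every grid point
        grid <- seq(0, 1, by = grid_step)
        prof <- vapply(grid, function(v) {
          stats::optimize(function(o) {
            th <- numeric(2)
            th[idx] <- v
            th[-idx] <- o
            fit$objective(th)
          }, c(0, 1))$objective
        }, numeric(1))
        inside <- grid[prof <= target]
        expect_gte(fit$ci95[p, 1], min(inside) - grid_step)
        expect_lte(fit$ci95[p, 1], min(inside) + grid_step)
        expect_gte(fit$ci95[p, 2], max(inside) - grid_step)
        expect_lte(fit$ci95[p, 2], max(inside) + grid_step)
        # the estimate lies inside its own CI
        expect_gte(fit$params[p], fit$ci95[p, 1])
        expect_lte(fit$params[p], fit$ci95[p, 2])
      }
    }
  })
})

test_that("non-overlapping CIs flag significance and overlapping ones do not", {
  truth_a <- isa_simulate(D = 0.5, g = 0.1)
  truth_b <- isa_simulate(D = 0.5, g = 0.5)
  fit_a <- isa_fit(cbind(truth_a, truth_a, truth_a))
  fit_b <- isa_fit(cbind(truth_b, truth_b, truth_b))
  expect_true(ci_overlap_significant(
    fit_a$ci95["g", 1], fit_a$ci95["g", 2],
    fit_b$ci95["g", 1], fit_b$ci95["g", 2]
  ))
  expect_false(ci_overlap_significant(
    fit_a$ci95["g", 1], fit_a$ci95["g", 2],
    fit_a$ci95["g", 1], fit_a$ci95["g", 2]
  ))
})

test_that("pooled SDs are floored and invalid inputs are rejected", {
  m <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(pooled_mid_sd(m), c(0.003, 0.003))
  expect_error(isa_fit(cbind(c(0.5, 0.6))), "sum to 1")
  expect_error(isa_fit(cbind(c(0.5, 0.5)), sigma = c(0, 0)), "positive")
})
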
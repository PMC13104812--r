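# Shared fitting machinery: multistart bounded weighted least squares and
# profile-likelihood ("parameter continuation") confidence intervals. Both
# the ISA fits and the lipid network fits go through these routines.

# Latin-hypercube multistart points over the parameter box, plus the box
# midpoint. Drawn under a local seed so calling code's RNG stream is left
# untouched (simulation studies generate noise around these fits).
multistart_points <- function(n_starts, lower, upper, seed) {
  p <- length(lower)
  pts <- withr::with_seed(seed, lhs::randomLHS(max(n_starts - 1L, 1L), p))
  pts <- sweep(sweep(pts, 2, upper - lower, "*"), 2, lower, "+")
  rbind((lower + upper) / 2, pts)[seq_len(n_starts), , drop = FALSE]
}

# Minimize sum(resid_fn(theta)^2) over a box from multiple starts, by
# bounded Levenberg-Marquardt on the residual vector. resid_fn must tolerate
# arguments marginally outside the box (finite-difference Jacobians);
# callers clamp internally.
fit_multistart <- function(resid_fn, lower, upper, n_starts = 20L, seed = 17L,
                           maxit = 200L) {
  starts <- multistart_points(n_starts, lower, upper, seed)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(starts[i, ], lower = lower, upper = upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = maxit)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$info %in% 1:4) any_conv <- TRUE
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")
  list(par = unname(best$par), value = best$deviance, converged = any_conv)
}

# Re-optimize all parameters except `index`, which is fixed at `value`.
# Returns the profiled SSR and the conditional optimum (used to warm-start
# the next continuation step).
profile_reopt <- function(resid_fn, index, value, other_start, lower, upper) {
  if (length(other_start) == 0L) {
    return(list(ssr = sum(resid_fn(value)^2), other = numeric(0)))
  }
  reduced <- function(po) {
    theta <- numeric(length(po) + 1L)
    theta[index] <- value
    theta[-index] <- po
    resid_fn(theta)
  }
  res <- tryCatch(
    minpack.lm::nls.lm(other_start, lower = lower[-index], upper = upper[-index],
      fn = reduced,
      control = minpack.lm::nls.lm.control(maxiter = 150L)
    ),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(ssr = sum(reduced(other_start)^2), other = other_start))
  }
  list(ssr = res$deviance, other = unname(res$par))
}

# Profile-likelihood CI for one parameter by continuation: step the parameter
# away from its estimate, re-fitting the others at each step, until the
# profiled SSR crosses ssr_min + qchisq(1 - alpha, 1); refine the crossing by
# bisection. If the bound is reached without a crossing the bound itself is
# the interval end (clamping rule). A profile that dips back below the
# threshold after crossing (non-monotone) triggers a full scan to the bound
# and the widest crossing is reported with a warning.
profile_continuation <- function(resid_fn, par_hat, ssr_min, index,
                                 lower, upper,
                                 threshold = stats::qchisq(0.95, 1),
                                 step = 0.01, refine_tol = 1e-4,
                                 confirm_steps = 5L) {
  target <- ssr_min + threshold
  one_side <- function(dir) {
    bound <- if (dir > 0) upper[index] else lower[index]
    v_in <- par_hat[index]
    other <- par_hat[-index]
    v <- v_in
    crossing <- NULL # c(v_in, v_out)
    nonmono <- FALSE
    repeat {
      v_next <- v + dir * step
      at_bound <- (dir > 0 && v_next >= bound) || (dir < 0 && v_next <= bound)
      if (at_bound) v_next <- bound
      pr <- profile_reopt(resid_fn, index, v_next, other, lower, upper)
      other <- pr$other
      if (pr$ssr > target) {
        if (is.null(crossing)) {
          crossing <- c(v, v_next)
          # confirm the profile keeps rising; a dip back below the threshold
          # marks a non-monotone profile
          vc <- v_next
          oc <- other
          for (k in seq_len(confirm_steps)) {
            vk <- vc + dir * step
            if ((dir > 0 && vk > bound) || (dir < 0 && vk < bound)) break
            pk <- profile_reopt(resid_fn, index, vk, oc, lower, upper)
            oc <- pk$other
            vc <- vk
            if (pk$ssr <= target) {
              nonmono <- TRUE
              break
            }
          }
          if (!nonmono) break
          crossing <- NULL
          v <- vc
          other <- oc
          if (v == bound) break
          next
        }
      } else {
        crossing <- NULL # still (or again) inside the confidence region
        v_in <- v_next
      }
      v <- v_next
      if (v == bound) break
    }
    if (nonmono) {
      warning(sprintf(
        "non-monotone SSR profile for parameter %d; reporting the widest crossing", index
      ))
    }
    if (is.null(crossing)) {
      return(bound) # clamped: region extends to the box bound
    }
    # bisection refinement of the crossing
    lo <- crossing[1]
    hi <- crossing[2]
    other_b <- other
    while (abs(hi - lo) > refine_tol) {
      mv <- (lo + hi) / 2
      pm <- profile_reopt(resid_fn, index, mv, other_b, lower, upper)
      other_b <- pm$other
      if (pm$ssr > target) hi <- mv else lo <- mv
    }
    (lo + hi) / 2
  }
  c(one_side(-1), one_side(+1))
}

#' Construct a fit-result object
#'
#' Container shared by [isa_fit()] and [network_fit()]: point estimates,
#' weighted SSR, per-parameter 95% profile-likelihood confidence intervals,
#' and the objective closure needed to recompute or extend profiles.
#'
#' @param params Named numeric vector of point estimates.
#' @param ssr Weighted sum of squared residuals at the optimum.
#' @param ci95 Matrix with rows per parameter and columns `lower`, `upper`
#'   (may contain `NA` when profiles were not requested).
#' @param n_obs Number of residuals entering the fit.
#' @param converged Did any optimization start converge.
#' @param n_starts Number of multistarts used.
#' @param resid_fn Weighted-residual closure over the full parameter vector
#'   (the objective is `sum(resid_fn(theta)^2)`).
#' @param lower,upper Parameter bounds.
#' @return An object of class `fit_result`.
#' @keywords internal
fit_result <- function(params, ssr, ci95, n_obs, converged, n_starts,
                       resid_fn, lower, upper) {
  stopifnot(!is.null(names(params)))
  structure(
    list(
      params = params, ssr = ssr, ci95 = ci95, n_obs = n_obs,
      converged = converged, n_starts = n_starts,
      resid_fn = resid_fn,
      objective = function(theta) sum(resid_fn(theta)^2),
      lower = lower, upper = upper
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> SSR %.6g on %d observations (%s, %d starts)\n",
    x$ssr, x$n_obs, if (x$converged) "converged" else "NOT converged", x$n_starts
  ))
  tab <- data.frame(
    estimate = x$params,
    lo95 = x$ci95[, 1],
    hi95 = x$ci95[, 2]
  )
  print(round(tab, 4))
  invisible(x)
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Steps the named parameter away from its estimate, re-optimizing all other
#' parameters at each step, until the weighted SSR exceeds
#' `SSR_min + qchisq(1 - alpha, 1)` (3.841 for `alpha = 0.05`); the crossing
#' is refined by bisection and clamped to the parameter bounds when the
#' region extends to them.
#'
#' @param fit A [fit_result] from [isa_fit()] or [network_fit()].
#' @param param_name Name of the parameter to profile.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @param step Continuation step size in parameter units.
#' @param refine_tol Bisection tolerance on the interval ends.
#' @return Numeric vector `c(lower, upper)`.
#' @export
profile_ci <- function(fit, param_name, alpha = 0.05, step = 0.01,
                       refine_tol = 1e-4) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("cannot profile a fit that did not converge")
  index <- match(param_name, names(fit$params))
  if (is.na(index)) stop("unknown parameter: ", param_name)
  profile_continuation(
    fit$resid_fn, fit$params, fit$ssr, index,
    fit$lower, fit$upper,
    threshold = stats::qchisq(1 - alpha, 1),
    step = step, refine_tol = refine_tol
  )
}

#' Significance by confidence-interval overlap
#'
#' Two fitted conditions are called significantly different exactly when
#' their 95% confidence intervals do not overlap — the decision rule used
#' for fitted fluxes throughout this package (no t-tests on fitted values).
#'
#' @param lo1,hi1 Interval for condition 1.
#' @param lo2,hi2 Interval for condition 2.
#' @return `TRUE` when the intervals are disjoint.
#' @export
ci_overlap_significant <- function(lo1, hi1, lo2, hi2) {
  hi1 < lo2 || hi2 < lo1
}
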
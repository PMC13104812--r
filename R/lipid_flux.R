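# Moiety-convolution lipid MFA. Complex lipids are assembled from moieties
# (glycerol or sphingoid backbone, acyl chains, sugar headgroup units); at
# isotopic pseudo-steady state the MID of newly synthesized material is the
# convolution of the moiety MIDs, and the measured pool is a mixture of that
# synthesis MID with pre-existing (unlabeled, post-correction) material:
#   species MID = (1 - g) * delta(M+0) + g * (moiety_1 (x) moiety_2 (x) ...)
# Moieties resolve to parameterized precursor pools (hexose M+6, HexNAc
# M+6/M+8, sialic acid M+9/M+11, acetyl M+2, Glyc3P M+3, serine-derived
# sphingoid M+2), to measured fixed inputs (e.g. the LacCer pool feeding GM3
# and Gb4), or to other species in the network.

#' Define a precursor pool
#'
#' A pool contributes one moiety MID. In `parameterized` mode the weight of
#' each labeled mass shift is a named free parameter (the unlabeled remainder
#' sits at M+0); in `fixed` mode the weights are supplied directly.
#'
#' @param pool_id Pool identifier.
#' @param shifts Integer labeled mass shifts (e.g. `c(9, 11)` for sialic
#'   acid made de novo from labeled vs partially labeled precursors).
#' @param param_names Names of the free enrichment parameters, one per shift
#'   (parameterized mode).
#' @param weights Fixed mole fractions per shift (fixed mode).
#' @param n_carbons Number of traceable carbons in the unit (defaults to
#'   `max(shifts)`).
#' @return An object of class `precursor_pool`.
#' @export
precursor_pool <- function(pool_id, shifts, param_names = NULL, weights = NULL,
                           n_carbons = max(shifts)) {
  shifts <- as.integer(shifts)
  if (any(shifts <= 0)) stop("labeled shifts must be positive (M+0 is the remainder)")
  if (max(shifts) > n_carbons + 2L) {
    stop("pool shifts exceed the unit's carbon count (plus hetero-label allowance)")
  }
  mode <- if (is.null(weights)) "parameterized" else "fixed"
  if (mode == "parameterized") {
    if (is.null(param_names) || length(param_names) != length(shifts)) {
      stop("parameterized pool needs one parameter name per labeled shift")
    }
  } else {
    if (length(weights) != length(shifts)) stop("one weight per shift required")
    if (any(weights < 0) || sum(weights) > 1 + 1e-8) {
      stop("fixed pool weights must be non-negative and sum to at most 1")
    }
  }
  structure(
    list(
      pool_id = pool_id, shifts = shifts, param_names = param_names,
      weights = weights, mode = mode, n_carbons = n_carbons
    ),
    class = "precursor_pool"
  )
}

# MID of a pool given the current parameter vector. Clamps the labeled
# weights into the simplex so finite-difference excursions during fitting
# stay valid; the fit objective adds a penalty for genuine violations.
pool_mid <- function(pool, params) {
  w <- if (pool$mode == "fixed") {
    pool$weights
  } else {
    unname(params[pool$param_names])
  }
  w <- pmin(pmax(w, 0), 1)
  tot <- sum(w)
  if (tot > 1) w <- w / tot
  v <- numeric(max(pool$shifts) + 1L)
  v[1L] <- 1 - sum(w)
  v[pool$shifts + 1L] <- w
  v
}

#' Define a lipid species
#'
#' @param species_id Species identifier (e.g. `"GM3"`).
#' @param moieties Character vector of moiety references, in convolution
#'   order; each must name a pool, a fixed measured input, or another
#'   species in the network.
#' @param g_param Name of the species' fractional-synthesis parameter
#'   (defaults to `g_<species_id>`).
#' @param measured Whether the species is observed (fitted against data).
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(species_id, moieties,
                          g_param = paste0("g_", species_id),
                          measured = TRUE) {
  stopifnot(is.character(moieties), length(moieties) >= 1L)
  structure(
    list(
      species_id = species_id, moieties = moieties,
      g_param = g_param, measured = measured
    ),
    class = "lipid_species"
  )
}

#' Assemble a lipid network
#'
#' @param species List of [lipid_species()] objects.
#' @param pools List of [precursor_pool()] objects.
#' @param fixed_input_ids Names of measured fixed inputs the network expects
#'   at simulation/fit time (e.g. `"LacCer_data"`).
#' @return An object of class `lipid_network` with the derived free-parameter
#'   set (all parameters bounded in `[0, 1]`).
#' @export
lipid_network <- function(species, pools, fixed_input_ids = character()) {
  names(species) <- vapply(species, `[[`, "", "species_id")
  names(pools) <- vapply(pools, `[[`, "", "pool_id")
  # free parameters: species g's plus parameterized pool enrichments
  free <- unlist(lapply(species, `[[`, "g_param"), use.names = FALSE)
  for (p in pools) {
    if (p$mode == "parameterized") free <- c(free, p$param_names)
  }
  free <- unique(free)
  # every moiety must resolve; the species dependency graph must be acyclic
  for (sp in species) {
    for (mo in sp$moieties) {
      if (!(mo %in% names(pools) || mo %in% fixed_input_ids || mo %in% names(species))) {
        stop(sprintf("unresolved moiety '%s' in species '%s'", mo, sp$species_id))
      }
    }
  }
  check_acyclic(species)
  structure(
    list(
      species = species, pools = pools,
      fixed_input_ids = fixed_input_ids, free_params = free
    ),
    class = "lipid_network"
  )
}

check_acyclic <- function(species) {
  state <- stats::setNames(rep(0L, length(species)), names(species))
  visit <- function(id) {
    if (state[[id]] == 1L) stop("cyclic species reference involving '", id, "'")
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (mo in species[[id]]$moieties) {
      if (mo %in% names(species)) visit(mo)
    }
    state[[id]] <<- 2L
  }
  for (id in names(species)) visit(id)
  invisible(TRUE)
}

#' @export
print.lipid_network <- function(x, ...) {
  cat(sprintf(
    "<lipid_network> %d species (%d measured), %d pools, %d free parameters\n",
    length(x$species), sum(vapply(x$species, `[[`, TRUE, "measured")),
    length(x$pools), length(x$free_params)
  ))
  for (sp in x$species) {
    cat(sprintf(
      "  %s = (1-%s)*M0 + %s*[%s]%s\n", sp$species_id, sp$g_param, sp$g_param,
      paste(sp$moieties, collapse = " (x) "),
      if (sp$measured) "" else "  (latent)"
    ))
  }
  invisible(x)
}

# Resolve one moiety reference to an MID, memoizing species MIDs.
resolve_mid <- function(ref, network, params, fixed_inputs, cache) {
  if (!is.null(cache$mids[[ref]])) return(cache$mids[[ref]])
  out <- if (ref %in% names(fixed_inputs)) {
    as.numeric(fixed_inputs[[ref]])
  } else if (ref %in% names(network$pools)) {
    pool_mid(network$pools[[ref]], params)
  } else if (ref %in% names(network$species)) {
    species_mid_raw(ref, network, params, fixed_inputs, cache)
  } else {
    stop("unresolved pool or input: ", ref)
  }
  cache$mids[[ref]] <- out
  out
}

species_mid_raw <- function(species_id, network, params, fixed_inputs, cache) {
  sp <- network$species[[species_id]]
  synth <- 1
  for (mo in sp$moieties) {
    synth <- conv_raw(synth, resolve_mid(mo, network, params, fixed_inputs, cache))
  }
  g <- min(max(unname(params[[sp$g_param]]), 0), 1)
  out <- g * synth
  out[1] <- out[1] + (1 - g)
  out
}

#' Simulate one species' MID from the network
#'
#' Pool-level mixing applied first, then convolution of the moiety MIDs in
#' order; the species MID is `(1 - g) * delta(M+0) + g * (moiety MIDs
#' convolved)`.
#'
#' @param species_id Which species to simulate.
#' @param network A [lipid_network()].
#' @param params Named vector covering the network's free parameters.
#' @param fixed_inputs Named list of measured MIDs for the network's fixed
#'   inputs.
#' @return The simulated MID.
#' @export
species_synth_mid <- function(species_id, network, params,
                              fixed_inputs = list()) {
  stopifnot(inherits(network, "lipid_network"))
  if (!species_id %in% names(network$species)) {
    stop("unknown species: ", species_id)
  }
  missing_par <- setdiff(network$free_params, names(params))
  if (length(missing_par)) {
    stop("missing parameters: ", paste(missing_par, collapse = ", "))
  }
  if (any(params < -1e-9) || any(params > 1 + 1e-9)) {
    stop("all network parameters must lie in [0, 1]")
  }
  missing_in <- setdiff(network$fixed_input_ids, names(fixed_inputs))
  if (length(missing_in)) {
    stop("missing fixed inputs: ", paste(missing_in, collapse = ", "))
  }
  for (nm in names(fixed_inputs)) assert_mid(fixed_inputs[[nm]], what = nm)
  cache <- new.env(parent = emptyenv())
  cache$mids <- list()
  species_mid_raw(species_id, network, params, fixed_inputs, cache)
}

#' Simulate all measured species of a network
#'
#' @inheritParams species_synth_mid
#' @return Named list of MIDs for every measured species.
#' @export
network_simulate <- function(network, params, fixed_inputs = list()) {
  ids <- names(network$species)[vapply(network$species, `[[`, TRUE, "measured")]
  stats::setNames(
    lapply(ids, species_synth_mid, network = network, params = params,
           fixed_inputs = fixed_inputs),
    ids
  )
}

#' Fatty acid elongation MID
#'
#' Each ELOVL elongation cycle condenses one 2-carbon acetyl unit onto the
#' base chain: the product MID is the base-chain MID convolved with the
#' acetyl-unit MID once per cycle (16:0 to 24:0 takes 4 cycles).
#'
#' @param base_chain MID of the starting chain.
#' @param n_cycles Non-negative number of elongation cycles.
#' @param acetyl_unit MID of the acetyl unit, typically `c(1 - D, 0, D)`.
#' @return The elongated-chain MID.
#' @export
elongation_mid <- function(base_chain, n_cycles, acetyl_unit) {
  if (n_cycles < 0 || n_cycles != round(n_cycles)) {
    stop("n_cycles must be a non-negative integer")
  }
  assert_mid(base_chain, what = "base chain MID")
  mid_convolve(base_chain, mid_nfold_convolve(acetyl_unit, as.integer(n_cycles)))
}

# Penalty for parameterized pools whose labeled weights exceed the simplex
# (sum > 1). Keeps L-BFGS-B inside the feasible region without hard
# constraints.
pool_simplex_penalty <- function(network, params, scale = 1e8) {
  pen <- 0
  for (p in network$pools) {
    if (p$mode == "parameterized" && length(p$param_names) > 1L) {
      excess <- sum(pmax(params[p$param_names], 0)) - 1
      if (excess > 0) pen <- pen + scale * excess^2
    }
  }
  pen
}

#' Fit a lipid network to replicate species MIDs
#'
#' Joint weighted least squares over all measured species' isotopologues and
#' replicates concurrently (residuals are concatenated, not averaged), with
#' multistart optimization over the `[0, 1]`-bounded free parameters and 95%
#' profile-likelihood confidence intervals by parameter continuation. A
#' parameter whose profile never crosses the chi-square threshold anywhere in
#' `[0, 1]` is flagged non-identifiable rather than assigned an arbitrary
#' interval.
#'
#' @param network A [lipid_network()].
#' @param measurements Named list (by measured species) of replicate MID
#'   matrices (rows = mass shifts, columns = replicates) or lists of MIDs.
#' @param fixed_inputs Named list of measured MIDs for fixed inputs.
#' @param sigma Optional named list of per-species SD vectors; defaults to
#'   [pooled_mid_sd()] per species.
#' @param sigma_floor Floor for pooled SDs.
#' @param n_starts Multistart points.
#' @param seed Seed for the local multistart stream.
#' @param compute_ci Compute profile CIs.
#' @param ci_params Parameters to profile (default: all free parameters).
#' @return A [fit_result] with an extra `identifiable` logical vector and
#'   the per-species residual breakdown in `species_ssr`.
#' @export
network_fit <- function(network, measurements, fixed_inputs = list(),
                        sigma = NULL, sigma_floor = 0.003,
                        n_starts = 10L, seed = 17L,
                        compute_ci = TRUE, ci_params = NULL) {
  stopifnot(inherits(network, "lipid_network"))
  meas_ids <- names(network$species)[vapply(network$species, `[[`, TRUE, "measured")]
  missing_meas <- setdiff(meas_ids, names(measurements))
  if (length(missing_meas)) {
    stop("measurements missing for species: ", paste(missing_meas, collapse = ", "))
  }
  missing_in <- setdiff(network$fixed_input_ids, names(fixed_inputs))
  if (length(missing_in)) {
    stop("missing fixed inputs: ", paste(missing_in, collapse = ", "))
  }
  mats <- lapply(meas_ids, function(id) replicate_matrix(measurements[[id]]))
  names(mats) <- meas_ids
  sig <- lapply(meas_ids, function(id) {
    if (!is.null(sigma) && !is.null(sigma[[id]])) {
      rep_len(sigma[[id]], nrow(mats[[id]]))
    } else {
      pooled_mid_sd(mats[[id]], floor = sigma_floor)
    }
  })
  names(sig) <- meas_ids

  free <- network$free_params
  p <- length(free)
  lower <- rep(0, p)
  upper <- rep(1, p)

  resid_fn <- function(theta) {
    theta <- pmin(pmax(theta, 0), 1)
    params <- stats::setNames(theta, free)
    cache <- new.env(parent = emptyenv())
    cache$mids <- list()
    res <- sqrt(pool_simplex_penalty(network, params))
    for (id in meas_ids) {
      sim <- species_mid_raw(id, network, params, fixed_inputs, cache)
      dat <- mats[[id]]
      if (length(sim) < nrow(dat)) sim <- c(sim, numeric(nrow(dat) - length(sim)))
      if (length(sim) > nrow(dat)) {
        extra <- sum(sim[(nrow(dat) + 1L):length(sim)])
        sim <- sim[seq_len(nrow(dat))]
        res <- c(res, extra / sigma_floor) # simulated mass beyond measured range
      }
      res <- c(res, as.vector((sim - dat) / sig[[id]]))
    }
    res
  }

  best <- fit_multistart(resid_fn, lower, upper, n_starts = n_starts, seed = seed)
  params <- stats::setNames(best$par, free)
  ci <- matrix(NA_real_, p, 2, dimnames = list(free, c("lower", "upper")))
  fit <- fit_result(
    params = params, ssr = best$value, ci95 = ci,
    n_obs = sum(vapply(mats, length, integer(1))),
    converged = best$converged, n_starts = n_starts,
    resid_fn = resid_fn, lower = lower, upper = upper
  )

  # per-species residual breakdown at the optimum
  cache <- new.env(parent = emptyenv())
  cache$mids <- list()
  fit$species_ssr <- vapply(meas_ids, function(id) {
    sim <- species_mid_raw(id, network, params, fixed_inputs, cache)
    dat <- mats[[id]]
    if (length(sim) < nrow(dat)) sim <- c(sim, numeric(nrow(dat) - length(sim)))
    sim <- sim[seq_len(nrow(dat))]
    sum(((sim - dat) / sig[[id]])^2)
  }, numeric(1))

  fit$identifiable <- stats::setNames(rep(NA, p), free)
  if (compute_ci && best$converged) {
    todo <- if (is.null(ci_params)) free else intersect(ci_params, free)
    for (nm in todo) {
      fit$ci95[nm, ] <- profile_ci(fit, nm)
      width <- fit$ci95[nm, 2] - fit$ci95[nm, 1]
      fit$identifiable[nm] <- width < 0.999 * (1 - 0)
    }
  }
  fit
}

#' Deconvolve a measured MID into moiety-labeling components
#'
#' Finds non-negative weights, summing to 1, that best reconstruct a
#' measured MID as a mixture of candidate basis MIDs (e.g. unlabeled,
#' ribose-labeled M+5, base-labeled, fully labeled components of a
#' nucleotide). Solved by nonnegativity-constrained least squares followed
#' by renormalization.
#'
#' @param measured The measured MID.
#' @param basis List of candidate component MIDs (padded to the measured
#'   length).
#' @return Named (if the basis list is named) weight vector with attribute
#'   `residual_norm`; a rank-deficient basis triggers a warning describing
#'   the ambiguity.
#' @export
moiety_deconvolve <- function(measured, basis) {
  assert_mid(measured, what = "measured MID")
  if (!is.list(basis) || length(basis) == 0L) stop("basis must be a non-empty list of MIDs")
  len <- length(measured)
  B <- vapply(basis, function(b) {
    assert_mid(b, what = "basis MID")
    mid_pad(b, max(len, length(b)))[seq_len(len)]
  }, numeric(len))
  B <- as.matrix(B)
  if (qr(B)$rank < ncol(B)) {
    warning(sprintf(
      "basis is rank-deficient (rank %d < %d components); weights along the nullspace are not determined by the data",
      qr(B)$rank, ncol(B)
    ))
  }
  sol <- pracma::lsqnonneg(B, as.numeric(measured))
  w <- pmax(sol$x, 0)
  resid <- sqrt(sum((B %*% w - measured)^2))
  if (sum(w) > 0) w <- w / sum(w)
  names(w) <- names(basis)
  attr(w, "residual_norm") <- resid
  w
}

#' Glycosphingolipid network preset
#'
#' Ganglioside/globoside network: GM3 and Gb4 are modeled from the measured
#' LacCer pool (`LacCer_data`) plus parameterized sugar units — sialic acid
#' with M+9/M+11 states (`s9`, `s11`) for GM3, and one hexose (`h`) plus one
#' HexNAc with M+6/M+8 states (`hn6`, `hn8`) for Gb4 (the Gb3 intermediate is
#' implicit; this reconstruction goes LacCer + Hex + HexNAc -> Gb4 directly).
#' LacCer itself is modeled from the measured ceramide pool (`Cer_data`)
#' plus two hexose units, which ties the hexose enrichment `h` to the LacCer
#' M+6/M+12 pattern.
#'
#' @return A [lipid_network()] requiring fixed inputs `Cer_data` and
#'   `LacCer_data`, with free parameters `g_LacCer`, `g_GM3`, `g_Gb4`, `h`,
#'   `s9`, `s11`, `hn6`, `hn8`.
#' @export
gsl_network <- function() {
  lipid_network(
    species = list(
      lipid_species("LacCer", c("Cer_data", "hexose", "hexose")),
      lipid_species("GM3", c("LacCer_data", "sialic")),
      lipid_species("Gb4", c("LacCer_data", "hexose", "hexnac"))
    ),
    pools = list(
      precursor_pool("hexose", shifts = 6L, param_names = "h"),
      precursor_pool("hexnac", shifts = c(6L, 8L), param_names = c("hn6", "hn8")),
      precursor_pool("sialic", shifts = c(9L, 11L), param_names = c("s9", "s11"))
    ),
    fixed_input_ids = c("Cer_data", "LacCer_data")
  )
}

#' Elongation / glycerolipid network preset
#'
#' LPC and SM species with 16:0 and 24:0 acyl chains. The 24:0 chain is a
#' latent pool elongated from the measured 16:0 chain by four acetyl-unit
#' cycles (parameter `D`, fractional renewal `g_acyl24`); LPC backbones draw
#' on the Glyc3P pool (M+3 weight `a3`); sphingoid backbones carry a
#' serine-derived M+2 unit (`e2`, decarboxylation of M+3 serine) condensed
#' with a 16:0 chain.
#'
#' @return A [lipid_network()] requiring fixed input `acyl16_data`, with
#'   free parameters `g_acyl24`, `g_LPC16`, `g_LPC24`, `g_SM34`, `g_SM42`,
#'   `a3`, `D`, `e2`.
#' @export
elongation_network <- function() {
  lipid_network(
    species = list(
      lipid_species("acyl24",
        c("acyl16_data", "acetyl", "acetyl", "acetyl", "acetyl"),
        measured = FALSE
      ),
      lipid_species("LPC16", c("glyc3p", "acyl16_data")),
      lipid_species("LPC24", c("glyc3p", "acyl24")),
      lipid_species("SM34", c("sphingoid", "acyl16_data", "acyl16_data")),
      lipid_species("SM42", c("sphingoid", "acyl16_data", "acyl24"))
    ),
    pools = list(
      precursor_pool("glyc3p", shifts = 3L, param_names = "a3"),
      precursor_pool("acetyl", shifts = 2L, param_names = "D"),
      precursor_pool("sphingoid", shifts = 2L, param_names = "e2")
    ),
    fixed_input_ids = "acyl16_data"
  )
}
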
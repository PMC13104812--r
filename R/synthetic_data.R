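# Synthetic tracing datasets with known ground truth. The generator forward-
# simulates corrected MIDs through the same public model operations the
# fitters use (isa_simulate, species_synth_mid, contaminate) — no private
# duplicate math — then adds replicate noise and natural-abundance
# contamination, and emits tables in the exact ingest formats. Defaults
# mirror the study design being emulated: three replicate slices per
# condition and per-isotopologue Gaussian noise of 0.003 mole fraction.

#' Synthetic dataset configuration
#'
#' @param scenario One of `"isa"`, `"elongation_network"`, `"gsl_network"`,
#'   `"turnover"`, `"full"`.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param n_replicates Replicate slices per condition (default 3).
#' @param noise_sd Additive Gaussian noise SD per isotopologue, in mole
#'   fraction (default 0.003); noisy MIDs are clipped at 0 and renormalized.
#' @param truth Named list of ground-truth parameters; defaults come from
#'   [scenario_truth()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(scenario = c("isa", "elongation_network", "gsl_network",
                                      "turnover", "full"),
                         seed = 1L, n_replicates = 3L, noise_sd = 0.003,
                         truth = NULL) {
  scenario <- match.arg(scenario)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  default <- scenario_truth(scenario)
  if (!is.null(truth)) default[names(truth)] <- truth
  unit_scale <- unlist(default[vapply(default, is.numeric, TRUE)])
  unit_scale <- unit_scale[!grepl("cal_|(^|\\.)N$|n_units", names(unit_scale))]
  if (length(unit_scale) && any(unit_scale < 0 | unit_scale > 1)) {
    stop("truth fractions must lie in [0, 1]")
  }
  structure(
    list(
      scenario = scenario, seed = as.integer(seed),
      n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
      truth = default
    ),
    class = "synth_config"
  )
}

#' Ground-truth parameter defaults per scenario
#'
#' These values define the simulated study conditions: palmitate synthesis
#' with a moderately enriched lipogenic acetyl pool; a GSL network with high
#' hexose and sialic enrichment feeding GM3/Gb4 on a lightly serine-labeled
#' ceramide; an elongation network with well-labeled Glyc3P, low acetyl
#' enrichment and modest sphingoid labeling; and a D2O arm with ~4.5%
#' body-water enrichment, a lipogenic liver and a salvage-dominated tumor.
#'
#' @param scenario Scenario name.
#' @return Named list of ground-truth parameters.
#' @export
scenario_truth <- function(scenario) {
  isa <- list(D = 0.5, g = 0.2, n_units = 8L)
  gsl <- list(
    g_LacCer = 0.5, g_GM3 = 0.4, g_Gb4 = 0.3,
    h = 0.9, s9 = 0.7, s11 = 0.1, hn6 = 0.5, hn8 = 0.2,
    cer_m2 = 0.1 # serine-derived M+2 labeling of the measured ceramide pool
  )
  elong <- list(
    g_acyl24 = 0.3, g_LPC16 = 0.5, g_LPC24 = 0.4, g_SM34 = 0.15, g_SM42 = 0.25,
    a3 = 0.6, D = 0.3, e2 = 0.15
  )
  turn <- list(
    p = 0.045, N = 22,
    fraction_new_tumor = 0.08, fraction_new_liver = 0.35,
    cal_slope = 120, cal_intercept = 5, cal_noise_sd = 0.5,
    biomass_asp_enrichment = 0.03, free_asp_enrichment = 0.30
  )
  switch(scenario,
    isa = isa,
    gsl_network = gsl,
    elongation_network = elong,
    turnover = turn,
    full = list(isa = isa, gsl_network = gsl, elongation_network = elong, turnover = turn)
  )
}

# One noisy replicate: additive Gaussian per isotopologue, clipped at 0,
# renormalized.
add_mid_noise <- function(x, sd) {
  if (sd == 0) return(as.numeric(x))
  y <- pmax(as.numeric(x) + stats::rnorm(length(x), 0, sd), 0)
  y / sum(y)
}

# Truth (corrected, tracer-only) MIDs per scenario, computed with the public
# model operations only.
scenario_truth_mids <- function(scenario, truth) {
  if (scenario == "isa") {
    list(
      palmitate = isa_simulate(truth$D, truth$g, truth$n_units),
      palmitate_g0 = isa_simulate(truth$D, 0, truth$n_units) # boundary: g = 0, D unidentifiable
    )
  } else if (scenario == "gsl_network") {
    net <- gsl_network()
    cer <- mid_mixture(list(mid_delta(0), mid_delta(2)), c(1 - truth$cer_m2, truth$cer_m2))
    pars <- unlist(truth[c("g_LacCer", "g_GM3", "g_Gb4", "h", "s9", "s11", "hn6", "hn8")])
    names(pars) <- c("g_LacCer", "g_GM3", "g_Gb4", "h", "s9", "s11", "hn6", "hn8")
    lac <- species_synth_mid("LacCer", net, pars, list(Cer_data = cer, LacCer_data = mid_delta(0)))
    fixed <- list(Cer_data = cer, LacCer_data = lac)
    out <- list(
      Cer = cer,
      LacCer = lac,
      GM3 = species_synth_mid("GM3", net, pars, fixed),
      Gb4 = species_synth_mid("Gb4", net, pars, fixed)
    )
    # boundary / non-identifiable case: no GM3 synthesis, sialic enrichment free
    pars0 <- pars
    pars0["g_GM3"] <- 0
    out$GM3_boundary <- species_synth_mid("GM3", net, pars0, fixed)
    out
  } else if (scenario == "elongation_network") {
    net <- elongation_network()
    acyl16 <- mid_delta(0) # long-chain fatty acids salvaged, not synthesized
    pars <- unlist(truth[c("g_acyl24", "g_LPC16", "g_LPC24", "g_SM34", "g_SM42", "a3", "D", "e2")])
    names(pars) <- c("g_acyl24", "g_LPC16", "g_LPC24", "g_SM34", "g_SM42", "a3", "D", "e2")
    fixed <- list(acyl16_data = acyl16)
    out <- list(
      acyl16 = acyl16,
      LPC16 = species_synth_mid("LPC16", net, pars, fixed),
      LPC24 = species_synth_mid("LPC24", net, pars, fixed),
      SM34 = species_synth_mid("SM34", net, pars, fixed),
      SM42 = species_synth_mid("SM42", net, pars, fixed),
      Glyc3P = pool_mid(net$pools[["glyc3p"]], pars)
    )
    pars0 <- pars
    pars0["g_SM34"] <- 0
    out$SM34_boundary <- species_synth_mid("SM34", net, pars0, fixed) # boundary: g = 0
    out
  } else {
    stop("no MID scenario: ", scenario)
  }
}

#' Generate a synthetic tracing dataset
#'
#' Deterministic given the seed. Emits a corrected-MID table (the oracle the
#' fitters consume), a raw table obtained by natural-abundance contamination
#' of the corrected replicates via [contaminate()], the metabolite
#' dictionary, the ground-truth record, and (for the turnover scenario)
#' calibration standards and sample tables.
#'
#' @param config A [synth_config()], or a scenario name (with `...` passed
#'   to [synth_config()]).
#' @param ... Passed to [synth_config()] when `config` is a scenario name.
#' @return An object of class `synth_dataset` with elements
#'   `corrected_mids`, `raw_mids` (long-format data.frames), `truth`,
#'   `dictionary`, `manifest`, and scenario-specific extras.
#' @export
generate_synth <- function(config, ...) {
  if (is.character(config)) config <- synth_config(config, ...)
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  dict <- default_dictionary()
  specs <- dictionary_specs(dict)
  ds <- list(
    config = config, truth = config$truth, dictionary = dict,
    corrected_mids = NULL, raw_mids = NULL
  )

  scenarios <- if (config$scenario == "full") {
    c("isa", "gsl_network", "elongation_network", "turnover")
  } else {
    config$scenario
  }

  corrected <- list()
  raw <- list()
  model_cache <- list()
  for (sc in scenarios) {
    truth_sc <- if (config$scenario == "full") config$truth[[sc]] else config$truth
    if (sc == "turnover") {
      ds <- c(ds, generate_turnover_tables(truth_sc, config))
      next
    }
    mids <- scenario_truth_mids(sc, truth_sc)
    for (an in names(mids)) {
      for (r in seq_len(config$n_replicates)) {
        samp <- sprintf("%s_rep%d", sc, r)
        noisy <- add_mid_noise(mids[[an]], config$noise_sd)
        corrected[[length(corrected) + 1L]] <- data.frame(
          sample_id = samp, analyte_id = an,
          mass_shift = seq_along(noisy) - 1L, value = noisy,
          value_type = "fraction", stringsAsFactors = FALSE
        )
        if (!an %in% names(model_cache)) {
          model_cache[[an]] <- build_correction_matrix(specs[[an]])
        }
        contam <- contaminate(noisy, model_cache[[an]])
        raw[[length(raw) + 1L]] <- data.frame(
          sample_id = samp, analyte_id = an,
          mass_shift = seq_along(contam) - 1L, value = contam * 1e6,
          value_type = "intensity", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(corrected)) {
    ds$corrected_mids <- do.call(rbind, corrected)
    ds$raw_mids <- do.call(rbind, raw)
  }
  ds$manifest <- list(
    scenario = config$scenario, seed = config$seed,
    n_replicates = config$n_replicates, noise_sd = config$noise_sd,
    rng = "base R Mersenne-Twister, set.seed(seed) then analytes in table order",
    truth = config$truth
  )
  class(ds) <- "synth_dataset"
  ds
}

# D2O calibration standards, tissue samples and biomass-pair table.
generate_turnover_tables <- function(truth, config) {
  known <- seq(0, 0.08, length.out = 6) # standards span 0-8% D2O
  signal <- truth$cal_intercept + truth$cal_slope * known +
    stats::rnorm(length(known), 0, truth$cal_noise_sd)
  standards <- data.frame(known_enrichment = known, signal = signal)

  plateau <- 1 - (1 - truth$p)^truth$N
  tissues <- c(tumor = truth$fraction_new_tumor, liver = truth$fraction_new_liver)
  samples <- do.call(rbind, lapply(names(tissues), function(tis) {
    e <- tissues[[tis]] * plateau
    data.frame(
      sample_id = sprintf("%s_rep%d", tis, seq_len(config$n_replicates)),
      tissue = tis,
      enrichment = pmin(pmax(e + stats::rnorm(config$n_replicates, 0, config$noise_sd), 0), 1),
      plasma_signal = truth$cal_intercept + truth$cal_slope * truth$p +
        stats::rnorm(config$n_replicates, 0, truth$cal_noise_sd),
      stringsAsFactors = FALSE
    )
  }))
  pairs <- data.frame(
    biomass_analyte = "aspartate_biomass", free_analyte = "aspartate",
    biomass_enrichment = truth$biomass_asp_enrichment,
    free_enrichment = truth$free_asp_enrichment,
    stringsAsFactors = FALSE
  )
  list(d2o_standards = standards, d2o_samples = samples, biomass_pairs = pairs)
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> scenario %s, seed %d, %d replicates, noise SD %.4g\n",
    x$config$scenario, x$config$seed, x$config$n_replicates, x$config$noise_sd
  ))
  if (!is.null(x$corrected_mids)) {
    cat(sprintf(
      "  %d corrected MID rows over analytes: %s\n",
      nrow(x$corrected_mids), paste(unique(x$corrected_mids$analyte_id), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Write a synthetic dataset to ingest-format files
#'
#' Writes `mids.csv` (raw intensities), `corrected_mids.csv` (oracle),
#' `dictionary.csv`, `truth.json`, `manifest.json`, and turnover tables when
#' present.
#'
#' @param ds A [generate_synth()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synth_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format_num_df(df), p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(ds$raw_mids)) wr(ds$raw_mids, "mids.csv")
  if (!is.null(ds$corrected_mids)) wr(ds$corrected_mids, "corrected_mids.csv")
  wr(ds$dictionary, "dictionary.csv")
  for (nm in c("d2o_standards", "d2o_samples", "biomass_pairs")) {
    if (!is.null(ds[[nm]])) wr(ds[[nm]], paste0(nm, ".csv"))
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(ds$manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

# Serialize numeric columns at fixed precision so re-runs are byte-identical.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.12g", df[[j]])
    }
  }
  df
}
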
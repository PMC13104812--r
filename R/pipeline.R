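# Pipeline: ingest -> natural-abundance correction -> enrichment summaries ->
# ISA / network fits -> turnover calculations -> tidy result tables and a run
# log, driven by a single manifest. Per-analyte failures are isolated and
# reported; the run continues. All floating-point outputs are serialized at
# fixed precision so a re-run with the same manifest and seed is
# bit-identical.

#' Read a long-format MID table
#'
#' @param x Path to a CSV with columns `sample_id`, `analyte_id`,
#'   `mass_shift`, `value`, `value_type` (`intensity` or `fraction`), or a
#'   data.frame already in that layout.
#' @return The validated data.frame.
#' @export
read_mid_table <- function(x) {
  tbl <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("sample_id", "analyte_id", "mass_shift", "value", "value_type")
  if (!all(need %in% names(tbl))) {
    stop("MID table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tbl$value_type %in% c("intensity", "fraction"))) {
    stop("value_type must be 'intensity' or 'fraction'")
  }
  if (any(tbl$value < 0)) stop("MID table contains negative values")
  tbl
}

#' Extract one analyte's replicate MID matrix from a long table
#'
#' Intensities are normalized to fractions per (sample, analyte) on the way
#' out; all the paper-level quantities are fractional.
#'
#' @param tbl A [read_mid_table()] table.
#' @param analyte Analyte id.
#' @param samples Optional sample subset (default: all samples carrying the
#'   analyte).
#' @return Matrix with rows = mass shifts (starting at M+0) and columns =
#'   samples.
#' @export
mid_matrix <- function(tbl, analyte, samples = NULL) {
  sub <- tbl[tbl$analyte_id == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte not present in MID table: ", analyte)
  if (is.null(samples)) samples <- unique(sub$sample_id)
  n_shift <- max(sub$mass_shift) + 1L
  m <- matrix(0, nrow = n_shift, ncol = length(samples),
              dimnames = list(NULL, samples))
  for (s in samples) {
    rows <- sub[sub$sample_id == s, , drop = FALSE]
    if (nrow(rows) == 0L) stop(sprintf("sample %s has no rows for analyte %s", s, analyte))
    v <- numeric(n_shift)
    v[rows$mass_shift + 1L] <- rows$value
    if (rows$value_type[1] == "intensity") v <- v / sum(v)
    m[, s] <- v
  }
  m
}

#' Build a run manifest
#'
#' @param mids MID table path or data.frame (raw or corrected).
#' @param dictionary Metabolite dictionary path or data.frame (default:
#'   [default_dictionary()]).
#' @param tracer Tracer label for the run log (e.g. `"U-13C6 glucose"`).
#' @param analyses Character subset of `c("isa", "gsl_network",
#'   "elongation_network", "turnover")`; empty means ingest + correction
#'   only.
#' @param isa_analyte Analyte fitted by the ISA analysis.
#' @param already_corrected Set `TRUE` when `mids` holds corrected MIDs
#'   (skips the correction step).
#' @param biomass_pairs Data.frame mapping biomass analytes to free-pool
#'   analytes for the turnover analysis (columns `biomass_analyte`,
#'   `free_analyte`).
#' @param out_dir Output directory (`NULL` for no files).
#' @param seed Seed recorded in the log and used for fit multistarts.
#' @param options Named list of overrides (`sigma_floor`, `n_starts_isa`,
#'   `n_starts_network`, `compute_ci`).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(mids, dictionary = NULL, tracer = "U-13C6 glucose",
                         analyses = character(), isa_analyte = "palmitate",
                         already_corrected = FALSE, biomass_pairs = NULL,
                         out_dir = NULL, seed = 17L, options = list()) {
  known <- c("isa", "gsl_network", "elongation_network", "turnover")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  opts <- list(sigma_floor = 0.003, n_starts_isa = 20L, n_starts_network = 10L,
               compute_ci = TRUE)
  opts[names(options)] <- options
  structure(
    list(
      mids = mids, dictionary = dictionary, tracer = tracer,
      analyses = analyses, isa_analyte = isa_analyte,
      already_corrected = already_corrected, biomass_pairs = biomass_pairs,
      out_dir = out_dir, seed = as.integer(seed), options = opts
    ),
    class = "run_manifest"
  )
}

#' Read a run manifest from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_manifest()].
#' @return A `run_manifest`.
#' @export
read_run_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_manifest, y)
}

#' Execute a full analysis run
#'
#' Ingest, per-analyte natural-abundance correction (failures isolated and
#' logged), per-sample enrichment table, requested fits, turnover ratios,
#' and tidy CSV outputs plus a plain-text run log.
#'
#' @param manifest A [run_manifest()] (or a YAML path).
#' @param synth_extras Optional [generate_synth()] dataset supplying the
#'   turnover-side tables (`d2o_standards`, `d2o_samples`, `biomass_pairs`)
#'   when the turnover analysis is requested.
#' @return A result bundle (list) with `corrected`, `enrichment`, `fits`,
#'   `turnover`, `issues`, and `log` elements, invisibly written to
#'   `out_dir` when set.
#' @export
run_pipeline <- function(manifest, synth_extras = NULL) {
  if (is.character(manifest)) manifest <- read_run_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  tbl <- read_mid_table(manifest$mids)
  dict <- if (is.null(manifest$dictionary)) {
    default_dictionary()
  } else if (is.character(manifest$dictionary)) {
    read_metabolite_dictionary(manifest$dictionary)
  } else {
    manifest$dictionary
  }
  specs <- dictionary_specs(dict)
  analytes <- unique(tbl$analyte_id)
  issues <- character()

  # --- correction ---------------------------------------------------------
  corrected_rows <- list()
  for (an in analytes) {
    res <- tryCatch({
      m <- mid_matrix(tbl, an)
      if (manifest$already_corrected) {
        cm <- m
      } else {
        if (!an %in% names(specs)) stop("analyte missing from dictionary: ", an)
        model <- build_correction_matrix(specs[[an]])
        cm <- apply(m, 2, function(v) as.numeric(correct_mid(v, model)))
      }
      do.call(rbind, lapply(colnames(m), function(s) {
        data.frame(
          sample_id = s, analyte_id = an,
          mass_shift = seq_len(nrow(cm)) - 1L,
          value = cm[, s], value_type = "fraction",
          stringsAsFactors = FALSE
        )
      }))
    }, error = function(e) {
      issues <<- c(issues, sprintf("correction failed for %s: %s", an, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) corrected_rows[[an]] <- res
  }
  corrected <- do.call(rbind, corrected_rows)
  rownames(corrected) <- NULL

  # --- enrichment summary (machine-readable twin of "total fraction labeled")
  enrichment <- do.call(rbind, lapply(names(corrected_rows), function(an) {
    m <- mid_matrix(corrected, an)
    data.frame(
      analyte_id = an, sample_id = colnames(m),
      enrichment = 1 - m[1L, ],
      mean_mass_shift = apply(m, 2, function(v) sum((seq_along(v) - 1) * v)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(enrichment) <- NULL

  # --- fits ---------------------------------------------------------------
  fits <- list()
  fit_tables <- list()
  opts <- manifest$options
  if ("isa" %in% manifest$analyses) {
    res <- tryCatch({
      m <- mid_matrix(corrected, manifest$isa_analyte)
      fit <- isa_fit(m,
        sigma_floor = opts$sigma_floor, n_starts = opts$n_starts_isa,
        seed = manifest$seed, compute_ci = opts$compute_ci
      )
      fits$isa <- fit
      data.frame(
        analysis = "isa", parameter = names(fit$params),
        estimate = unname(fit$params),
        lo95 = fit$ci95[, 1], hi95 = fit$ci95[, 2],
        ssr = fit$ssr, n_obs = fit$n_obs, stringsAsFactors = FALSE
      )
    }, error = function(e) {
      issues <<- c(issues, paste("isa fit failed:", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) fit_tables$isa <- res
  }
  for (netname in intersect(c("gsl_network", "elongation_network"), manifest$analyses)) {
    res <- tryCatch({
      net <- if (netname == "gsl_network") gsl_network() else elongation_network()
      meas_ids <- names(net$species)[vapply(net$species, `[[`, TRUE, "measured")]
      measurements <- lapply(meas_ids, function(id) mid_matrix(corrected, id))
      names(measurements) <- meas_ids
      fixed <- lapply(net$fixed_input_ids, function(fid) {
        an <- sub("_data$", "", fid)
        rowMeans(mid_matrix(corrected, an))
      })
      names(fixed) <- net$fixed_input_ids
      fit <- network_fit(net, measurements, fixed,
        sigma_floor = opts$sigma_floor, n_starts = opts$n_starts_network,
        seed = manifest$seed, compute_ci = opts$compute_ci
      )
      fits[[netname]] <- fit
      data.frame(
        analysis = netname, parameter = names(fit$params),
        estimate = unname(fit$params),
        lo95 = fit$ci95[, 1], hi95 = fit$ci95[, 2],
        ssr = fit$ssr, n_obs = fit$n_obs, stringsAsFactors = FALSE
      )
    }, error = function(e) {
      issues <<- c(issues, paste(netname, "fit failed:", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) fit_tables[[netname]] <- res
  }
  fit_table <- if (length(fit_tables)) do.call(rbind, fit_tables) else NULL
  if (!is.null(fit_table)) rownames(fit_table) <- NULL

  # --- turnover -----------------------------------------------------------
  turnover <- NULL
  if ("turnover" %in% manifest$analyses) {
    turnover <- tryCatch({
      out <- list()
      if (!is.null(synth_extras) && !is.null(synth_extras$d2o_standards)) {
        cal <- calibrate_d2o(
          synth_extras$d2o_standards$known_enrichment,
          synth_extras$d2o_standards$signal
        )
        samp <- synth_extras$d2o_samples
        p_hat <- mean(predict_d2o_enrichment(cal, samp$plasma_signal))
        N <- if (!is.null(synth_extras$truth$N)) {
          synth_extras$truth$N
        } else if (!is.null(synth_extras$truth$turnover$N)) {
          synth_extras$truth$turnover$N
        } else {
          22
        }
        samp$fraction_new <- vapply(
          samp$enrichment,
          function(e) d2o_fraction_new(e, p = p_hat, N = N, enrichment_is_scalar = TRUE),
          numeric(1)
        )
        out$d2o <- samp
        out$calibration <- cal
        out$p_hat <- p_hat
      }
      pairs <- manifest$biomass_pairs
      if (is.null(pairs) && !is.null(synth_extras)) pairs <- synth_extras$biomass_pairs
      if (!is.null(pairs)) {
        if (all(c("biomass_enrichment", "free_enrichment") %in% names(pairs))) {
          pairs$fractional_synthesis <- biomass_fractional_synthesis(
            pairs$biomass_enrichment, pairs$free_enrichment
          )
        } else {
          pairs$fractional_synthesis <- mapply(function(b, f) {
            bm <- mean(1 - mid_matrix(corrected, b)[1L, ])
            fm <- mean(1 - mid_matrix(corrected, f)[1L, ])
            biomass_fractional_synthesis(bm, fm)
          }, pairs$biomass_analyte, pairs$free_analyte)
        }
        out$biomass <- pairs
      }
      out
    }, error = function(e) {
      issues <<- c(issues, paste("turnover analysis failed:", conditionMessage(e)))
      NULL
    })
  }

  # --- run log and outputs ------------------------------------------------
  log_lines <- c(
    sprintf("fluxslice %s", as.character(utils::packageVersion("fluxslice"))),
    sprintf("tracer: %s", manifest$tracer),
    sprintf("seed: %d", manifest$seed),
    sprintf("analyses: %s", if (length(manifest$analyses)) paste(manifest$analyses, collapse = ", ") else "(none)"),
    sprintf("sigma floor: %g mole fraction", opts$sigma_floor),
    sprintf("multistarts: isa %d, network %d", opts$n_starts_isa, opts$n_starts_network),
    "fitted-flux comparisons use the 95% CI overlap rule, never t-tests",
    "group comparisons of enrichments/abundances: two-tailed t-test, NO multiple-testing correction",
    sprintf("analytes corrected: %d of %d", length(corrected_rows), length(analytes)),
    if (length(issues)) paste("ISSUE:", issues) else "no issues"
  )

  bundle <- list(
    corrected = corrected, enrichment = enrichment,
    fits = fits, fit_table = fit_table, turnover = turnover,
    issues = issues, log = log_lines, manifest = manifest
  )
  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format_num_df(corrected),
      file.path(manifest$out_dir, "corrected_mids.csv"),
      row.names = FALSE, quote = FALSE
    )
    utils::write.csv(format_num_df(enrichment),
      file.path(manifest$out_dir, "enrichment.csv"),
      row.names = FALSE, quote = FALSE
    )
    if (!is.null(fit_table)) {
      utils::write.csv(format_num_df(fit_table),
        file.path(manifest$out_dir, "fits.csv"),
        row.names = FALSE, quote = FALSE
      )
    }
    if (!is.null(turnover$d2o)) {
      utils::write.csv(format_num_df(turnover$d2o),
        file.path(manifest$out_dir, "d2o_fraction_new.csv"),
        row.names = FALSE, quote = FALSE
      )
    }
    if (!is.null(turnover$biomass)) {
      utils::write.csv(format_num_df(turnover$biomass),
        file.path(manifest$out_dir, "biomass_synthesis.csv"),
        row.names = FALSE, quote = FALSE
      )
    }
    writeLines(log_lines, file.path(manifest$out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
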
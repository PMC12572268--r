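#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end attribution run, with the
#' analysis defaults: `epsilon = 1` in the log transform, lag set
#' \{1, 2, 3, 4, 9\} months, 90th-percentile extreme threshold, facilities
#' dropped above 90% missingness, and 4.4 ANC visits per pregnancy. A
#' resolved copy of the configuration is written alongside every run's
#' outputs.
#'
#' @param grid_csv,facilities_csv,panel_csv Paths to the input files.
#' @param closures_csv Optional closure-registry CSV (`NULL` = none).
#' @param out_dir Output artifact directory (created if absent).
#' @param epsilon Offset inside the log response transform.
#' @param lags Integer month lags for the index table.
#' @param percentile_q Percentile defining an extreme month.
#' @param threshold_pool `"all_cells"` pools every grid cell-month for the
#'   percentile; `"facility_cells"` pools only facility-assigned cells.
#' @param sparse_missing_threshold Missing fraction above which a facility is
#'   excluded.
#' @param visits_per_pregnancy ANC visits per pregnancy for conversion.
#' @param pregnancy_mode `"per_pregnancy"` or `"per_visit"` (see
#'   [affected_pregnancies]).
#' @param candidate_terms Precipitation terms offered to stepwise selection;
#'   `NULL` = every index column of the lag set.
#' @param base_terms Fixed non-climate model terms.
#' @param seed Integer seed recorded with the run (the fit itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid_csv, facilities_csv, panel_csv,
                            closures_csv = NULL,
                            out_dir = "ancrain-run",
                            epsilon = 1,
                            lags = c(1L, 2L, 3L, 4L, 9L),
                            percentile_q = 90,
                            threshold_pool = c("all_cells", "facility_cells"),
                            sparse_missing_threshold = 0.9,
                            visits_per_pregnancy = 4.4,
                            pregnancy_mode = c("per_pregnancy", "per_visit"),
                            candidate_terms = NULL,
                            base_terms = default_base_terms(),
                            seed = 1L) {
  structure(
    list(
      grid_csv = grid_csv, facilities_csv = facilities_csv,
      panel_csv = panel_csv, closures_csv = closures_csv, out_dir = out_dir,
      epsilon = epsilon, lags = sort(unique(as.integer(lags))),
      percentile_q = percentile_q,
      threshold_pool = match.arg(threshold_pool),
      sparse_missing_threshold = sparse_missing_threshold,
      visits_per_pregnancy = visits_per_pregnancy,
      pregnancy_mode = match.arg(pregnancy_mode),
      candidate_terms = candidate_terms,
      base_terms = base_terms,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Structured stage logging to stderr; failures abort naming the stage.
run_stage <- function(log, stage, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf(
    "[%s] %s (%.2fs)", format(t0, "%H:%M:%S"), stage,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  log$stages <- c(log$stages, list(list(
    stage = stage, at = format(t0, "%Y-%m-%dT%H:%M:%S")
  )))
  list(result = result, log = log)
}

#' Run the full attribution pipeline
#'
#' Executes the analysis end to end from files on disk: read and validate
#' inputs, assign facilities to grid cells, build the precipitation index
#' table, clean the panel (closure zeros, sparse-facility exclusion, altitude
#' imputation), assemble the design, fit the precipitation-free model M0,
#' select the precipitation model M1 by backward stepwise AIC, compare them
#' by likelihood ratio, and derive the disruption series and national
#' summary. All artifacts, a resolved-config record and a run manifest are
#' written to `config$out_dir`; identical inputs and configuration give
#' identical outputs.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the fitted models, LR test, disruption
#'   series, summary and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(stages = list())

  st <- run_stage(log, "read_inputs", {
    list(
      grid = read_precip_grid(config$grid_csv),
      facilities = read_facilities(config$facilities_csv),
      panel = read_anc_panel(config$panel_csv),
      closures = if (!is.null(config$closures_csv)) {
        read_closures(config$closures_csv)
      } else {
        closure_registry()
      }
    )
  })
  log <- st$log; inputs <- st$result
  message("  facilities: ", nrow(inputs$facilities),
    "; panel rows: ", nrow(inputs$panel))

  st <- run_stage(log, "assign_cells", assign_grid_cells(inputs$facilities, inputs$grid))
  log <- st$log; facilities <- st$result

  st <- run_stage(log, "climate_indices", {
    build_index_table(inputs$grid, lags = config$lags)
  })
  log <- st$log; indices <- st$result

  st <- run_stage(log, "clean_panel", {
    panel <- apply_closure_zeros(inputs$panel, inputs$closures)
    exclude_sparse_facilities(panel, config$sparse_missing_threshold)
  })
  log <- st$log; panel <- st$result
  message("  panel rows after cleaning: ", nrow(panel))

  st <- run_stage(log, "covariates", impute_altitude(facilities))
  log <- st$log; facilities <- st$result
  if (is.null(facilities$min_distance)) {
    facilities$min_distance <- min_distance_to_closest(facilities)
  }

  candidates <- config$candidate_terms %||% index_columns(config$lags)
  st <- run_stage(log, "assemble_design", {
    assemble_design(
      panel, facilities, indices,
      precip_terms = candidates,
      base_terms = config$base_terms,
      epsilon = config$epsilon
    )
  })
  log <- st$log; design <- st$result
  message("  design rows: ", nrow(design))

  st <- run_stage(log, "fit_models", {
    m0 <- fit_ols(design, config$base_terms)
    sel <- backward_stepwise(design, config$base_terms, candidates)
    list(m0 = m0, m1 = sel$model, path = sel$path)
  })
  log <- st$log; fits <- st$result

  st <- run_stage(log, "lr_test", likelihood_ratio_test(fits$m0, fits$m1))
  log <- st$log; lrt <- st$result

  st <- run_stage(log, "attribution", {
    pool <- if (config$threshold_pool == "all_cells") {
      indices$cumulative
    } else {
      indices$cumulative[indices$cell_id %in% unique(facilities$cell_id)]
    }
    threshold <- percentile_threshold(pool[!is.na(pool)], config$percentile_q)
    series <- disruption_series(fits$m0, fits$m1, design, threshold)
    total <- sum(predict_counts(fits$m0, design))
    summary <- aggregate_disruption(series, total)
    summary$affected_pregnancies <- affected_pregnancies(
      summary$deficit_services, config$visits_per_pregnancy, config$pregnancy_mode
    )
    list(threshold = threshold, series = series, summary = summary)
  })
  log <- st$log; attrib <- st$result

  st <- run_stage(log, "write_artifacts", {
    paths <- list(
      index_table = file.path(config$out_dir, "index_table.csv"),
      m0 = file.path(config$out_dir, "m0.json"),
      m1 = file.path(config$out_dir, "m1.json"),
      lr_test = file.path(config$out_dir, "lr_test.json"),
      stepwise_path = file.path(config$out_dir, "stepwise_path.csv"),
      disruption_series = file.path(config$out_dir, "disruption_series.csv"),
      summary = file.path(config$out_dir, "summary.csv"),
      report = file.path(config$out_dir, "model_report.txt"),
      resolved_config = file.path(config$out_dir, "resolved_config.json"),
      manifest = file.path(config$out_dir, "run_manifest.json")
    )
    write_index_table(indices, paths$index_table)
    write_fitted_model(fits$m0, paths$m0)
    write_fitted_model(fits$m1, paths$m1)
    jsonlite::write_json(unclass(lrt), paths$lr_test, auto_unbox = TRUE, digits = NA)
    utils::write.csv(fits$path, paths$stepwise_path, row.names = FALSE)
    utils::write.csv(attrib$series, paths$disruption_series, row.names = FALSE)
    utils::write.csv(attrib$summary, paths$summary, row.names = FALSE)
    writeLines(model_report(fits$m0, fits$m1), paths$report)
    jsonlite::write_json(
      unclass(config), paths$resolved_config,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    paths
  })
  log <- st$log; paths <- st$result

  manifest <- list(
    stages = log$stages,
    n_facilities = nrow(facilities),
    n_panel_rows = nrow(panel),
    n_design_rows = nrow(design),
    extreme_threshold_mm = attrib$threshold,
    seed = config$seed
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(
    facilities = facilities, indices = indices, design = design,
    m0 = fits$m0, m1 = fits$m1, stepwise_path = fits$path,
    lr_test = lrt, threshold_mm = attrib$threshold,
    series = attrib$series, summary = attrib$summary, paths = paths
  ))
}

#' Simulate a full synthetic input set to disk
#'
#' Convenience wrapper binding the synthetic-data generators: writes the
#' rainfall grid, facility table, service-count panel (with missingness
#' applied) and closure registry into a directory, ready for [run_pipeline].
#'
#' @param config A [sim_config].
#' @param out_dir Output directory.
#' @param n_closures Closed facilities to simulate.
#' @return Named list of file paths, invisibly.
#' @export
simulate_inputs <- function(config, out_dir, n_closures = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- generate_precip_grid(config)
  facilities <- generate_facilities(config)
  facilities <- assign_grid_cells(facilities, grid)
  indices <- build_index_table(grid, lags = config$lags)
  panel <- generate_anc_counts(facilities, indices, config)
  closures <- generate_closures(facilities, config, n_closures)
  panel <- apply_missingness(panel, closures, config)
  paths <- list(
    grid = file.path(out_dir, "precip_grid.csv"),
    facilities = file.path(out_dir, "facilities.csv"),
    panel = file.path(out_dir, "anc_panel.csv"),
    closures = file.path(out_dir, "closures.csv")
  )
  write_precip_grid(grid, paths$grid)
  write_facilities(facilities[, setdiff(names(facilities), "cell_id")], paths$facilities)
  write_anc_panel(panel, paths$panel)
  write_closures(closures, paths$closures)
  invisible(paths)
}
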
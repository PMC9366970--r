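#' Pipeline run configuration
#'
#' @param target_areas path to the target-area GeoJSON.
#' @param establishments path to the establishment file (`.json` popularity
#'   dialect, or `.csv` coordinates/categories).
#' @param scans path to the scans CSV.
#' @param cpat path to the CPAT CSV.
#' @param popularity optional flat popularity CSV to attach when
#'   `establishments` is a CSV.
#' @param category_map optional path to a raw,type CSV mapping; default
#'   [default_category_map()].
#' @param unmapped unmapped-category policy (`"other"` or `"error"`).
#' @param buffer_radius_m buffer radius in meters.
#' @param window two integers, the sensitivity window hours.
#' @param imputation_policy `"strict"` or `"lenient"` (see
#'   [impute_popularity()]).
#' @param corstr GEE working correlation.
#' @param outdir output directory for written artifacts.
#' @return a validated `run_config` list.
#' @export
run_config <- function(target_areas, establishments, scans, cpat,
                       popularity = NULL, category_map = NULL,
                       unmapped = c("other", "error"),
                       buffer_radius_m = 250, window = c(9, 19),
                       imputation_policy = c("strict", "lenient"),
                       corstr = c("exchangeable", "independence"),
                       outdir = "activation_out") {
  cfg <- list(
    target_areas = target_areas, establishments = establishments,
    scans = scans, cpat = cpat, popularity = popularity,
    category_map = category_map, unmapped = match.arg(unmapped),
    buffer_radius_m = buffer_radius_m, window = window,
    imputation_policy = match.arg(imputation_policy),
    corstr = match.arg(corstr), outdir = outdir
  )
  for (f in c("target_areas", "establishments", "scans", "cpat")) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]])) {
      pa_stop_structural(sprintf("input file for '%s' not found: %s",
                                 f, cfg[[f]] %||% "NULL"))
    }
  }
  if (!is_finite_num(cfg$buffer_radius_m) || cfg$buffer_radius_m <= 0) {
    pa_stop_structural("buffer radius must be positive")
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("config file not found: %s", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

pa_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      if (inherits(e, "pa_error")) {
        stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                            class = class(e)))
      }
    }
  )
}

pa_log <- function(lines, stage, msg) {
  c(lines, sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stage, msg))
}

#' Run the full analysis pipeline
#'
#' Reads the four inputs, maps establishment categories to broad types,
#' builds 250 m (configurable) buffers around each park's target areas,
#' computes per-park exposure measures from the observed popularity data and
#' again after nearest same-type imputation onto the full listing, fits the
#' three-model Poisson GEE battery on both measure sets, and correlates the
#' two sets of park measures. All artifacts are written under
#' `config$outdir`.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return (invisibly) a list with the in-memory results (`contexts`,
#'   `batteries`, `comparisons`, `provenance`) and `paths` to the written
#'   artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    pa_stop_structural("'config' must be a run_config or a path to one")
  }
  log_lines <- character(0)

  areas <- pa_stage("read_target_areas", read_target_areas(config$target_areas))
  est <- pa_stage("read_establishments", {
    if (grepl("\\.json$", config$establishments, ignore.case = TRUE)) {
      read_establishments_json(config$establishments)
    } else {
      e <- read_establishments_csv(config$establishments)
      if (!is.null(config$popularity)) {
        e <- read_popularity_csv(config$popularity, e)
      }
      e
    }
  })
  scans <- pa_stage("read_scans", read_scans(config$scans))
  cpat <- pa_stage("read_cpat", read_cpat(config$cpat))
  log_lines <- pa_log(log_lines, "inputs", sprintf(
    "%d target areas, %d establishments (%d with popularity), %d scans, %d parks with CPAT",
    nrow(areas), nrow(est), sum(has_weekly(est)), nrow(scans), nrow(cpat)))

  cmap <- if (is.null(config$category_map)) default_category_map() else
    read_category_map(config$category_map)
  est$type <- pa_stage("categories",
                       map_category(est$raw_category, cmap, config$unmapped))

  buffers <- pa_stage("buffers", {
    lapply(split(areas, areas$park_id), build_buffer,
           radius_m = config$buffer_radius_m)
  })
  log_lines <- pa_log(log_lines, "buffers",
                      sprintf("%d park buffers at %.0f m", length(buffers),
                              config$buffer_radius_m))

  observed <- est[has_weekly(est), , drop = FALSE]
  ctx_obs <- pa_stage("measures_observed",
                      compute_park_contexts(observed, buffers, cpat,
                                            window = config$window))
  imp <- pa_stage("imputation",
                  impute_popularity(est, policy = config$imputation_policy))
  ctx_full <- pa_stage("measures_imputed",
                       compute_park_contexts(imp$establishments, buffers, cpat,
                                             window = config$window))
  log_lines <- pa_log(log_lines, "imputation",
                      sprintf("%d establishments imputed (%d fallbacks)",
                              nrow(imp$provenance), sum(imp$provenance$fallback)))

  tab_obs <- pa_stage("analysis_table", build_analysis_table(scans, ctx_obs))
  tab_full <- pa_stage("analysis_table", build_analysis_table(scans, ctx_full))
  bat_obs <- pa_stage("modeling", run_model_battery(tab_obs, corstr = config$corstr))
  bat_full <- pa_stage("modeling", run_model_battery(tab_full, corstr = config$corstr))
  log_lines <- pa_log(log_lines, "modeling", sprintf(
    "battery fitted on %d scans in %d parks (observed and imputed measure sets)",
    nrow(tab_obs), length(buffers)))

  comparisons <- pa_stage("compare_measures", {
    do.call(rbind, lapply(c("n_establishments", "n_types", "l2"), function(v) {
      cm <- compare_measures(ctx_obs[[v]], ctx_full[[v]])
      data.frame(measure = v, r = cm$r, p = cm$p, n = cm$n,
                 stringsAsFactors = FALSE)
    }))
  })

  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  measures <- rbind(cbind(set = "observed", ctx_obs),
                    cbind(set = "imputed", ctx_full))
  fits <- rbind(cbind(set = "observed", battery_results(bat_obs)),
                cbind(set = "imputed", battery_results(bat_full)))
  paths <- list(
    measures = file.path(outdir, "park_measures.csv"),
    analysis_table = file.path(outdir, "analysis_table.csv"),
    fits = file.path(outdir, "model_results.csv"),
    comparisons = file.path(outdir, "measure_comparisons.csv"),
    provenance = file.path(outdir, "imputation_provenance.csv"),
    buffers = file.path(outdir, "buffers.geojson"),
    log = file.path(outdir, "run.log")
  )
  utils::write.csv(measures, paths$measures, row.names = FALSE)
  utils::write.csv(tab_obs[, setdiff(names(tab_obs), "cluster")],
                   paths$analysis_table, row.names = FALSE)
  utils::write.csv(fits, paths$fits, row.names = FALSE)
  utils::write.csv(comparisons, paths$comparisons, row.names = FALSE)
  write_provenance(imp$provenance, paths$provenance)
  point_only <- all(vapply(buffers, function(b) {
    all(vapply(b$geoms, function(g) g$type, character(1)) == "point")
  }, logical(1)))
  if (point_only) write_buffers(buffers, paths$buffers) else paths$buffers <- NULL
  log_lines <- pa_log(log_lines, "done", sprintf("artifacts written to %s", outdir))
  writeLines(log_lines, paths$log)

  invisible(list(
    contexts = list(observed = ctx_obs, imputed = ctx_full),
    batteries = list(observed = bat_obs, imputed = bat_full),
    comparisons = comparisons,
    provenance = imp$provenance,
    paths = paths
  ))
}
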
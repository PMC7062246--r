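#' Config-driven end-to-end workflow
#'
#' One seeded entry point chaining the full pipeline: occurrence cleaning ->
#' background generation (both schemes unless configured) -> predictor
#' harmonization and collinearity screen -> five algorithms x background
#' methods with cross-validation and gates -> four thresholds, binary maps,
#' equal-weight ensembles, MESS, permutation importance -> management-unit
#' risk tables -> a manifest recording every seed, setting and gate decision.
#' The human-intervention junctures of the original process (variable
#' pre-selection, overfitting review) are explicit config fields, so a run
#' is fully replayable from its manifest.
#'
#' @name workflow_cli
NULL

#' Build and validate a run configuration
#'
#' Inputs may be file paths (CSV occurrences, `.asc` rasters, GeoJSON units)
#' or in-memory objects; in-memory inputs are materialized into the output
#' directory during the run so the manifest references files only.
#'
#' @param species_name label used in outputs.
#' @param occurrences path to an occurrence CSV or an [occurrence_set].
#' @param predictors named list of raster paths or a [raster_stack]; the
#'   first layer is the template grid.
#' @param out_dir output directory (created).
#' @param seed master seed; all stage seeds derive from it.
#' @param candidate_variables predictor subset to consider (the explicit
#'   human pre-selection step); default all.
#' @param priority `"auto"` or an ordered variable list for the screen.
#' @param correlation_threshold collinearity cutoff (default 0.7).
#' @param occurrence_filters list of [filter_occurrences] arguments.
#' @param dedup list of [deduplicate_and_flag] arguments.
#' @param background list: `methods` (subset of `"kde"`, `"target"`),
#'   `n` (default 10000), `bandwidth`, `isopleth_mass` (0.99),
#'   `per_axis_buffer`.
#' @param target_occurrences path/[occurrence_set] with a `lifeform` column
#'   (required when the target method is configured).
#' @param lifeform lifeform filter for the target guild.
#' @param algorithms algorithm subset (default all five).
#' @param algorithm_overrides named list of per-algorithm settings lists.
#' @param gates list with `overfit_gap` (0.05) and `min_cv_auc` (0.7).
#' @param cv_folds cross-validation folds (default 10).
#' @param threshold_rules rules to compute (default all four).
#' @param risk_rule rule used for the risk table (default `"pct1"`).
#' @param min_agreement ensemble agreement for "suitable" in the risk table
#'   (default at least half the retained models).
#' @param units list of [management_unit]s or a GeoJSON path (optional).
#' @param independent_points path or [occurrence_set] (optional).
#' @return validated `run_config` object.
#' @export
run_config <- function(species_name, occurrences, predictors, out_dir,
                       seed = 1,
                       candidate_variables = NULL, priority = "auto",
                       correlation_threshold = 0.7,
                       occurrence_filters = list(),
                       dedup = list(),
                       background = list(),
                       target_occurrences = NULL, lifeform = "grass",
                       algorithms = c("glm_stepwise", "mars", "brt", "rf",
                                      "maxent_like"),
                       algorithm_overrides = list(),
                       gates = list(overfit_gap = 0.05, min_cv_auc = 0.7),
                       cv_folds = 10,
                       threshold_rules = c("mpp", "pct1", "pct10", "mss"),
                       risk_rule = "pct1", min_agreement = NULL,
                       units = NULL, independent_points = NULL) {
  background <- utils::modifyList(list(methods = c("kde", "target"),
                                       n = 10000, bandwidth = "auto",
                                       isopleth_mass = 0.99,
                                       per_axis_buffer = FALSE),
                                  background)
  gates <- utils::modifyList(list(overfit_gap = 0.05, min_cv_auc = 0.7),
                             gates)
  background$methods <- match.arg(background$methods, c("kde", "target"),
                                  several.ok = TRUE)
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if ("target" %in% background$methods && is.null(target_occurrences))
    stop("config error: target background method needs target_occurrences")
  for (p in c(if (is.character(occurrences)) occurrences,
              if (is.list(predictors) && !inherits(predictors, "raster_stack"))
                unlist(Filter(is.character, predictors)),
              if (is.character(target_occurrences)) target_occurrences,
              if (is.character(units)) units,
              if (is.character(independent_points)) independent_points))
    if (!file.exists(p)) stop("config error: path does not exist: ", p)
  structure(list(species_name = species_name, occurrences = occurrences,
                 predictors = predictors, out_dir = out_dir,
                 seed = as.integer(seed),
                 candidate_variables = candidate_variables,
                 priority = priority,
                 correlation_threshold = correlation_threshold,
                 occurrence_filters = occurrence_filters, dedup = dedup,
                 background = background,
                 target_occurrences = target_occurrences,
                 lifeform = lifeform, algorithms = algorithms,
                 algorithm_overrides = algorithm_overrides, gates = gates,
                 cv_folds = cv_folds, threshold_rules = threshold_rules,
                 risk_rule = risk_rule, min_agreement = min_agreement,
                 units = units, independent_points = independent_points),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON config file (the manifest's `config` block round-trips).
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$algorithm_overrides <- lapply(j$algorithm_overrides, as.list)
  do.call(run_config, j)
}

stage_seed <- function(master, offset) (master + offset) %% 2147483647L

load_config_occurrences <- function(x, crs_id = "planar") {
  if (inherits(x, "occurrence_set")) return(x)
  load_occurrences(x, column_map = c(
    species_name = "species_name", x = "x", y = "y",
    event_date = "event_date", record_type = "record_type",
    coordinate_uncertainty_m = "coordinate_uncertainty_m",
    source = "source"), crs_id = crs_id)
}

#' Load a target-guild occurrence table (canonical columns + lifeform)
#' @param path CSV with the [occurrence_set] columns plus `lifeform`.
#' @param crs_id reference-system label.
#' @export
load_target_occurrences <- function(path, crs_id = "planar") {
  s <- load_config_occurrences(path, crs_id)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(raw$lifeform))
    stop("target occurrence file lacks a 'lifeform' column: ", path)
  s$records$lifeform <- raw$lifeform
  s
}

load_config_stack <- function(predictors, candidate_variables = NULL) {
  if (inherits(predictors, "raster_stack")) {
    stack <- predictors
  } else {
    stack <- raster_stack(lapply(predictors, read_asc))
  }
  if (!is.null(candidate_variables)) {
    miss <- setdiff(candidate_variables, names(stack))
    if (length(miss)) stop("candidate variable(s) not in predictors: ",
                           paste(miss, collapse = ", "))
    stack <- raster_stack(stack$layers[candidate_variables])
  }
  stack
}

#' Execute the workflow
#'
#' @param config a [run_config].
#' @return (invisibly) a list with the fitted models, ensembles, tables and
#'   the manifest; all artifacts are also written under `config$out_dir`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "rasters"), showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("habsuit")),
                   species_name = config$species_name,
                   master_seed = config$seed, stages = list())

  # --- occurrences -----------------------------------------------------
  log_msg("[occurrences] loading and cleaning")
  occ_raw <- load_config_occurrences(config$occurrences)
  occ <- do.call(filter_occurrences, c(list(occ_raw),
                                       config$occurrence_filters))
  template_stack <- load_config_stack(config$predictors,
                                      config$candidate_variables)
  template <- stack_template(template_stack)
  dedup_args <- utils::modifyList(list(snap_cell_m = template$cell_size),
                                  config$dedup)
  occ <- do.call(deduplicate_and_flag, c(list(occ), dedup_args))
  if (nrow(occ$records) == 0) stop("stage occurrences: no records retained")
  write_occurrences(occ, file.path(out, "occurrences_clean.csv"))
  manifest$stages$occurrences <- list(
    input = if (is.character(config$occurrences)) config$occurrences
            else file.path(out, "occurrences_clean.csv"),
    retained = nrow(occ$records), filter_log = as.list(occ$filter_log))

  # --- predictors (harmonize + materialize) ----------------------------
  log_msg("[predictors] harmonizing %d candidate layers",
          length(names(template_stack)))
  stack <- raster_stack(lapply(template_stack$layers, parc_harmonize,
                               template = template))
  pred_paths <- list()
  for (nm in names(stack)) {
    p <- file.path(out, "rasters", paste0("predictor_", nm, ".asc"))
    write_asc(stack$layers[[nm]], p)
    pred_paths[[nm]] <- p
  }

  # --- backgrounds ------------------------------------------------------
  backgrounds <- list()
  if ("kde" %in% config$background$methods) {
    log_msg("[background] kde sampling (n = %d)", config$background$n)
    kde <- fit_kde(occ, bandwidth = config$background$bandwidth)
    extent <- buffered_mcp(occ, per_axis = config$background$per_axis_buffer)
    backgrounds$kde <- sample_kde_background(
      kde, extent, config$background$n,
      seed = stage_seed(config$seed, 101L), template = template)
    write_background(backgrounds$kde, file.path(out, "background_kde.csv"),
                     file.path(out, "extent_kde.geojson"))
  }
  if ("target" %in% config$background$methods) {
    log_msg("[background] target-guild sampling")
    tgt <- if (inherits(config$target_occurrences, "occurrence_set"))
      config$target_occurrences else
      load_target_occurrences(config$target_occurrences)
    tgt_path <- file.path(out, "target_occurrences.csv")
    utils::write.csv(tgt$records, tgt_path, row.names = FALSE)
    kde <- fit_kde(occ, bandwidth = config$background$bandwidth)
    region <- kde_isopleth(kde, config$background$isopleth_mass, template)
    backgrounds$target <- sample_target_background(
      tgt, config$lifeform, region, config$background$n,
      seed = stage_seed(config$seed, 202L))
    write_background(backgrounds$target,
                     file.path(out, "background_target.csv"))
  }
  manifest$stages$background <- lapply(backgrounds, function(b)
    list(method = b$method, n = b$n, seed = b$seed,
         extent = b$extent$construction))

  # --- design tables + collinearity screen ------------------------------
  first_method <- names(backgrounds)[1]
  tables <- lapply(backgrounds, function(b)
    extract_design_table(stack, occ, b))
  log_msg("[screen] correlation screen on the %s design table", first_method)
  screen <- max_correlation_matrix(tables[[first_method]],
                                   threshold = config$correlation_threshold)
  screen <- select_uncorrelated(screen, priority = config$priority)
  write_correlation_report(screen, file.path(out, "correlation_matrix.csv"),
                           file.path(out, "correlation_removals.csv"))
  keep_vars <- screen$retained
  screened_stack <- raster_stack(stack$layers[keep_vars])
  tables <- lapply(tables, function(t) {
    t2 <- t[, c("point_id", "x", "y", "response", keep_vars)]
    class(t2) <- class(t)
    t2
  })
  manifest$stages$screen <- list(retained = keep_vars,
                                 removed = names(screen$removed),
                                 threshold = config$correlation_threshold)

  # --- models -----------------------------------------------------------
  models <- list()
  fold_rows <- list()
  idx <- 0L
  for (method in names(backgrounds)) {
    for (alg in config$algorithms) {
      idx <- idx + 1L
      id <- paste(alg, method, sep = "_")
      log_msg("[models] fitting %s", id)
      spec <- model_spec(alg, method,
                         settings = config$algorithm_overrides[[alg]] %||% list(),
                         seed = stage_seed(config$seed, 1000L + 10L * idx))
      res <- evaluate_model(spec, tables[[method]], k = config$cv_folds,
                            overfit_gap = config$gates$overfit_gap,
                            min_cv_auc = config$gates$min_cv_auc)
      models[[id]] <- res$model
      fold_rows[[id]] <- cbind(model = id, res$cv$folds)
      manifest$stages$models[[id]] <- list(
        algorithm = alg, background_method = method,
        seed = spec$seed, settings = res$model$spec$settings,
        retuned = res$retuned,
        variables_used = res$model$variables_used,
        train_auc = res$model$train_auc, cv_auc = res$model$cv_auc,
        gates = res$model$gates)
    }
  }
  retained <- Filter(function(m) !m$gates$dropped, models)
  log_msg("[models] %d of %d models retained", length(retained),
          length(models))

  metrics <- do.call(rbind, lapply(names(models), function(id) {
    m <- models[[id]]
    rbind(cbind(model = id,
                metric_row(threshold_metrics(
                  predict_scores(m, tables[[m$spec$background_method]]),
                  tables[[m$spec$background_method]]$response,
                  sens_eq_spec_threshold(
                    predict_scores(m, tables[[m$spec$background_method]]),
                    tables[[m$spec$background_method]]$response),
                  split = "train"))),
          cbind(model = id, metric_row(m$cv_metrics)))
  }))
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, fold_rows), file.path(out, "cv_folds.csv"),
                   row.names = FALSE)

  # --- predictions, thresholds, ensembles -------------------------------
  suit_rasters <- list()
  for (id in names(retained)) {
    suit_rasters[[id]] <- predict_raster(retained[[id]], screened_stack)
    write_asc(suit_rasters[[id]],
              file.path(out, "rasters", paste0("suitability_", id, ".asc")))
  }
  ensembles <- list()
  thresholds_log <- list()
  if (length(retained)) {
    for (rule in config$threshold_rules) {
      binaries <- list()
      for (id in names(retained)) {
        m <- retained[[id]]
        tbl <- tables[[m$spec$background_method]]
        scores <- predict_scores(m, tbl)
        thr <- compute_threshold(rule, scores[tbl$response == 1],
                                 all_scores = list(scores = scores,
                                                   labels = tbl$response))
        thresholds_log[[rule]][[id]] <- thr$value
        binaries[[id]] <- binarize_raster(suit_rasters[[id]], thr)
        write_asc(binaries[[id]],
                  file.path(out, "rasters",
                            paste0("binary_", rule, "_", id, ".asc")))
      }
      ensembles[[rule]] <- build_ensemble(binaries,
                                          rule = structure(list(kind = rule),
                                                           class = "threshold_rule"))
      write_asc(ensembles[[rule]]$ensemble,
                file.path(out, "rasters", paste0("ensemble_", rule, ".asc")))
    }
  }
  manifest$stages$thresholds <- thresholds_log

  # --- MESS (one per background method; shared by its models) -----------
  mess <- list()
  for (method in names(backgrounds)) {
    mess[[method]] <- mess_surface(screened_stack, tables[[method]])
    write_asc(mess[[method]]$mess,
              file.path(out, "rasters", paste0("mess_", method, ".asc")))
  }

  # --- permutation importance ------------------------------------------
  imp_rows <- list()
  for (id in names(retained)) {
    imp <- permutation_importance(retained[[id]],
                                  tables[[retained[[id]]$spec$background_method]],
                                  seed = stage_seed(config$seed, 7000L + length(imp_rows)))
    imp_rows[[id]] <- cbind(model = id, imp$per_variable)
  }
  importance <- if (length(imp_rows)) do.call(rbind, imp_rows) else
    data.frame(model = character(), variable = character(),
               delta_auc = numeric(), percent_contribution = numeric(),
               rank = integer())
  utils::write.csv(importance, file.path(out, "importance.csv"),
                   row.names = FALSE)

  # --- risk + independent evaluation ------------------------------------
  risk <- NULL
  units_path <- NULL
  if (!is.null(config$units)) {
    units <- config$units
    if (is.character(units)) {
      units_path <- config$units
      polys <- read_polygons_geojson(units)
      units <- lapply(stats::setNames(names(polys), names(polys)),
                      function(nm) management_unit(nm, polys[[nm]]))
    } else {
      units_path <- file.path(out, "units.geojson")
      write_polygons_geojson(lapply(units, `[[`, "polygon"), units_path)
    }
    if (!is.null(ensembles[[config$risk_rule]])) {
      ens <- ensembles[[config$risk_rule]]
      min_agree <- config$min_agreement %||% ceiling(ens$retained_count / 2)
      risk <- zonal_risk_summary(ens, units, min_agreement = min_agree,
                                 occurrences = occ)
      utils::write.csv(risk, file.path(out, "risk.csv"), row.names = FALSE)
      manifest$stages$risk <- list(rule = config$risk_rule,
                                   min_agreement = min_agree,
                                   n_units = length(units))
    }
  }
  indep <- NULL
  indep_path <- NULL
  if (!is.null(config$independent_points)) {
    pts <- load_config_occurrences(config$independent_points)
    indep_path <- file.path(out, "independent_points.csv")
    utils::write.csv(pts$records, indep_path, row.names = FALSE)
    if (length(ensembles)) {
      indep <- independent_point_evaluation(ensembles, pts)
      utils::write.csv(indep, file.path(out, "independent_evaluation.csv"),
                       row.names = FALSE)
    }
  }

  # --- manifest ---------------------------------------------------------
  manifest$config <- list(
    species_name = config$species_name,
    occurrences = file.path(out, "occurrences_clean.csv"),
    predictors = pred_paths,
    out_dir = out, seed = config$seed,
    candidate_variables = names(stack),
    priority = config$priority,
    correlation_threshold = config$correlation_threshold,
    occurrence_filters = config$occurrence_filters,
    dedup = dedup_args,
    background = config$background,
    target_occurrences = if ("target" %in% config$background$methods)
      file.path(out, "target_occurrences.csv") else NULL,
    lifeform = config$lifeform,
    algorithms = config$algorithms,
    algorithm_overrides = config$algorithm_overrides,
    gates = config$gates, cv_folds = config$cv_folds,
    threshold_rules = config$threshold_rules,
    risk_rule = config$risk_rule, min_agreement = config$min_agreement,
    units = units_path, independent_points = indep_path)
  manifest$retained_models <- names(retained)
  manifest$dropped_models <- lapply(
    Filter(function(m) m$gates$dropped, models),
    function(m) m$gates$reason)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(occurrences = occ, backgrounds = backgrounds,
                 screen = screen, tables = tables, models = models,
                 retained = retained, ensembles = ensembles, mess = mess,
                 metrics = metrics, importance = importance, risk = risk,
                 independent = indep, manifest = manifest))
}

#' Re-run a workflow from its manifest
#'
#' The manifest's `config` block references only materialized files, so
#' `replay_workflow(manifest_path, new_out_dir)` reproduces the run
#' byte-identically (the cleaning and harmonization stages are idempotent).
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the replay.
#' @export
replay_workflow <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$out_dir <- out_dir
  cfg$predictors <- as.list(cfg$predictors)
  cfg$algorithm_overrides <- lapply(cfg$algorithm_overrides, as.list)
  cfg$occurrence_filters <- as.list(cfg$occurrence_filters)
  cfg$dedup <- as.list(cfg$dedup)
  cfg$background <- as.list(cfg$background)
  cfg$gates <- as.list(cfg$gates)
  run_workflow(do.call(run_config, cfg))
}
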
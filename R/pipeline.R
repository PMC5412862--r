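#' Derive a stage seed from the run seed
#'
#' One global seed fans out to per-stage seeds through a stable polynomial
#' hash of the stage name, so any stage can be re-run on its own with the
#' same stream it saw inside the full pipeline. Result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return integer stage seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 65521) * 32003 + h + 1)
}

#' Build the model covariate stack from generated layers
#'
#' Derives the distance-to-class companions (`blt_dst`, `roa_dst`) of the
#' binary layers, passes the continuous layers through, and optionally
#' appends an event-density layer aggregated onto the covariate grid.
#'
#' @param covariates named list from [generate_covariates()].
#' @param event_grid optional `raster_grid` of event counts (any lattice;
#'   aggregated sum-preservingly onto the covariate grid as layer `twe`).
#' @return a `covariate_stack`.
#' @export
build_model_stack <- function(covariates, event_grid = NULL) {
  layers <- list(
    blt_cls = covariates$blt_cls,
    blt_dst = distance_raster(covariates$blt_cls),
    lig = covariates$lig,
    ele = covariates$ele,
    roa_cls = covariates$roa_cls,
    roa_dst = distance_raster(covariates$roa_cls)
  )
  roles <- NULL
  if (!is.null(event_grid)) {
    layers$twe <- event_grid
    roles <- c(twe = "count")
  }
  assemble_stack(layers, descriptor = grid_descriptor(covariates$blt_cls),
                 roles = roles)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the paired with/without-events experiment
#'
#' The full two-arm analysis from one config: generate the synthetic
#' region, floor-grid the point events at a fine cell size and aggregate
#' them onto the covariate grid, build two covariate stacks (with and
#' without the event-density layer), summarize both over the coarse units,
#' fit a forest per arm on coarse-unit log density, predict per-pixel
#' weighting layers, dasymetrically redistribute the coarse census counts,
#' validate both maps against the fine-level census, and difference the
#' two accuracy reports (without - with). Deterministic given the config.
#'
#' @param config a [landscape_config()].
#' @param n_trees trees per forest (default 500).
#' @param transform response transform for [fit_forest()].
#' @param tweet_cell_factor the event grid is `cell_size /
#'   tweet_cell_factor` (default 10: a 0.001-degree event lattice under a
#'   0.01-degree covariate grid).
#' @param outdir if non-NULL, all artifacts (rasters, tables, the
#'   comparison CSV, a run log) are written there.
#' @param quiet suppress progress messages (default TRUE).
#' @return object of class `experiment_result`: `truth`, `event_grid`,
#'   `stacks`, `fits`, `weights`, `maps` (redistributed grids), `reports`
#'   (per-arm `accuracy_report`s), `comparison` (a `comparison_report`,
#'   without - with).
#' @export
run_experiment <- function(config, n_trees = 500,
                           transform = c("log", "identity"),
                           tweet_cell_factor = 10,
                           outdir = NULL, quiet = TRUE) {
  transform <- match.arg(transform)
  t0 <- Sys.time()
  pipeline_log(quiet, "[synthesize] seed %d, %dx%d grid",
               config$seed, config$grid_shape[1], config$grid_shape[2])
  truth <- generate_truth(config)

  pipeline_log(quiet, "[grid-events] %d events", nrow(truth$events))
  desc <- list(origin = config$origin, cell_size = config$cell_size,
               shape = config$grid_shape)
  ev_grid <- aggregate_points(truth$events,
                              cell_size = config$cell_size / tweet_cell_factor,
                              extent = grid_extent(desc))
  twe <- align_to_grid(ev_grid, desc, method = "sum")

  pipeline_log(quiet, "[build-stack] deriving distance layers")
  stack_without <- build_model_stack(truth$covariates)
  stack_with <- build_model_stack(truth$covariates, event_grid = twe)

  fit_arm <- function(stack, arm) {
    zt <- zonal_summarize(stack, truth$admin_coarse)
    fit <- fit_forest(zt, n_trees = n_trees,
                      seed = derive_seed(config$seed, paste0("forest_", arm)),
                      transform = transform)
    pipeline_log(quiet, "[fit %s] OOB var explained %.3f", arm,
                 fit$oob_var_explained)
    w <- predict_weights(fit, stack)
    map <- dasymetric_redistribute(w, truth$admin_coarse)
    nfall <- attr(map, "n_fallback_units")
    if (nfall > 0) {
      pipeline_log(quiet, "[redistribute %s] %d unit(s) fell back to uniform",
                   arm, nfall)
    }
    pred <- aggregate_to_units(map, truth$admin_fine)
    obs <- data.frame(unit_id = truth$admin_fine$units$unit_id,
                      pop_count = truth$admin_fine$units$pop_count)
    rep_ <- accuracy(pred, obs, label = paste0(arm, "_events"))
    list(table = zt, fit = fit, weights = w, map = map, report = rep_)
  }
  without <- fit_arm(stack_without, "without")
  with_ <- fit_arm(stack_with, "with")
  comparison <- compare_accuracy(without$report, with_$report)

  res <- structure(list(
    config = config, truth = truth, event_grid = twe,
    stacks = list(without = stack_without, with = stack_with),
    tables = list(without = without$table, with = with_$table),
    fits = list(without = without$fit, with = with_$fit),
    weights = list(without = without$weights, with = with_$weights),
    maps = list(without = without$map, with = with_$map),
    reports = list(without = without$report, with = with_$report),
    comparison = comparison
  ), class = "experiment_result")

  if (!is.null(outdir)) write_experiment(res, outdir)
  pipeline_log(quiet, "[done] %.1fs; RMSE without %.2f, with %.2f",
               as.numeric(difftime(Sys.time(), t0, units = "secs")),
               without$report$rmse, with_$report$rmse)
  res
}

#' Write experiment artifacts to disk
#'
#' Plain-text serialization of everything a run produced: the synthetic
#' region, the event-density layer, both weighting layers and population
#' maps, the per-pixel difference map, importance tables, and the
#' three-row accuracy comparison CSV.
#'
#' @param res an `experiment_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_truth(res$truth, file.path(outdir, "synthetic"))
  write_raster_asc(res$event_grid, file.path(outdir, "twe.asc"))
  for (arm in c("without", "with")) {
    write_raster_asc(res$weights[[arm]],
                     file.path(outdir, paste0("weights_", arm, ".asc")))
    write_raster_asc(res$maps[[arm]],
                     file.path(outdir, paste0("population_", arm, ".asc")))
    fit <- res$fits[[arm]]
    utils::write.csv(
      data.frame(covariate = names(fit$importance),
                 importance = as.numeric(fit$importance),
                 oob_var_explained = fit$oob_var_explained),
      file.path(outdir, paste0("importance_", arm, ".csv")),
      row.names = FALSE)
  }
  write_raster_asc(difference_map(res$maps$with, res$maps$without),
                   file.path(outdir, "difference_with_minus_without.asc"))
  write_comparison_csv(res$comparison, file.path(outdir, "accuracy_comparison.csv"))
  invisible(outdir)
}

#' Multi-seed paired-experiment summary
#'
#' Repeats [run_experiment()] over a vector of seeds (all other config
#' fields fixed) and tabulates the per-seed headline quantities: fine-level
#' RMSE and %RMSE per arm, their paired difference, the OOB variance
#' explained per arm, and the event covariate's permutation-importance rank
#' in the with-events arm (1 = most important).
#'
#' @param seeds integer vector of run seeds.
#' @param config_args named list of [landscape_config()] overrides shared
#'   by all runs.
#' @param n_trees,transform,tweet_cell_factor passed to [run_experiment()].
#' @return data.frame, one row per seed.
#' @export
paired_experiment_summary <- function(seeds, config_args = list(),
                                      n_trees = 500, transform = "log",
                                      tweet_cell_factor = 10) {
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(landscape_config, c(list(seed = s), config_args))
    res <- run_experiment(cfg, n_trees = n_trees, transform = transform,
                          tweet_cell_factor = tweet_cell_factor)
    imp <- res$fits$with$importance
    data.frame(
      seed = s,
      rmse_without = res$reports$without$rmse,
      rmse_with = res$reports$with$rmse,
      rmse_diff = res$comparison$diff[["rmse"]],
      pct_rmse_without = res$reports$without$pct_rmse,
      pct_rmse_with = res$reports$with$pct_rmse,
      mae_diff = res$comparison$diff[["mae"]],
      oob_without = res$fits$without$oob_var_explained,
      oob_with = res$fits$with$oob_var_explained,
      twe_rank = rank(-imp, ties.method = "min")[["twe"]],
      n_covariates_with = length(imp)
    )
  })
  do.call(rbind, rows)
}
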
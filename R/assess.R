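#' Aggregate a population grid to admin units
#'
#' Zonal sums of a persons-per-pixel grid over (typically finer) admin
#' units — the cross-scale validation step: a map built from coarse-level
#' counts is summed to fine units and compared with the fine-level census.
#' Units with zero pixels are dropped with a warning.
#'
#' @param pop a `raster_grid` of persons per pixel.
#' @param admin an `admin_layer`.
#' @return data.frame with `unit_id` and `pred_count`.
#' @export
aggregate_to_units <- function(pop, admin) {
  stopifnot_same_grid(grid_descriptor(pop), admin$grid,
                      "population grid and admin layer")
  m <- as.vector(admin$membership)
  v <- as.vector(pop$values)
  keep <- !is.na(m) & !is.na(v)
  s <- rowsum(v[keep], m[keep])
  pred <- setNames(rep(NA_real_, nrow(admin$units)), admin$units$unit_id)
  pred[rownames(s)] <- s[, 1]
  out <- data.frame(unit_id = admin$units$unit_id,
                    pred_count = as.numeric(pred[as.character(admin$units$unit_id)]))
  if (anyNA(out$pred_count)) {
    warning(sum(is.na(out$pred_count)),
            " unit(s) dropped in aggregation: no valid pixels")
    out <- out[!is.na(out$pred_count), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Prediction accuracy over census units
#'
#' RMSE, percent RMSE and MAE of predicted versus observed unit counts:
#' `rmse = sqrt(mean((pred - obs)^2))`, `mae = mean(|pred - obs|)`,
#' `pct_rmse = 100 * rmse / mean(obs)`. The denominator of %RMSE is the
#' mean observed count over exactly the units entering the comparison.
#'
#' @param pred,obs either named numeric vectors (names = unit ids) or
#'   data.frames with `unit_id` and a count column (`pred_count` /
#'   `pop_count` / the single non-id column). Ids must match one-to-one;
#'   mismatches raise an error listing the offending ids.
#' @param label model label carried into reports.
#' @return object of class `accuracy_report`: list with `label`, `rmse`,
#'   `pct_rmse`, `mae`, `n_units`, `mean_obs`, and the per-unit `residuals`
#'   (pred - obs, named by unit id).
#' @export
accuracy <- function(pred, obs, label = "model") {
  pv <- as_unit_counts(pred, c("pred_count", "count"))
  ov <- as_unit_counts(obs, c("pop_count", "obs_count", "count"))
  only_p <- setdiff(names(pv), names(ov))
  only_o <- setdiff(names(ov), names(pv))
  if (length(only_p) || length(only_o)) {
    stop("unit id mismatch; only in pred: [",
         paste(utils::head(only_p, 10), collapse = ", "),
         "]; only in obs: [", paste(utils::head(only_o, 10), collapse = ", "), "]")
  }
  ov <- ov[names(pv)]
  n <- length(pv)
  if (n < 1L) stop("no units to compare")
  if (mean(ov) <= 0) stop("mean observed count must be > 0")
  res <- pv - ov
  rmse <- sqrt(mean(res^2))
  mae <- mean(abs(res))
  structure(list(label = label, rmse = rmse,
                 pct_rmse = 100 * rmse / mean(ov), mae = mae,
                 n_units = n, mean_obs = mean(ov), residuals = res),
            class = "accuracy_report")
}

#' Construct an accuracy report from published summary values
#'
#' Builds an `accuracy_report` directly from its summary statistics — for
#' example, rows of a published accuracy table — so [compare_accuracy()]
#' can reproduce difference rows without the unit-level data.
#'
#' @param label model label.
#' @param rmse,mae error statistics in persons.
#' @param pct_rmse percent RMSE; defaults to `100 * rmse / mean_obs` when
#'   `mean_obs` is given.
#' @param n_units,mean_obs optional unit count and mean observed count.
#' @return an `accuracy_report` (without per-unit residuals).
#' @export
accuracy_report <- function(label, rmse, mae, pct_rmse = NULL,
                            n_units = NA_integer_, mean_obs = NA_real_) {
  if (is.null(pct_rmse)) {
    if (is.na(mean_obs)) stop("give either pct_rmse or mean_obs")
    pct_rmse <- 100 * rmse / mean_obs
  }
  if (rmse < mae) stop("rmse cannot be smaller than mae")
  structure(list(label = label, rmse = rmse, pct_rmse = pct_rmse, mae = mae,
                 n_units = n_units, mean_obs = mean_obs, residuals = NULL),
            class = "accuracy_report")
}

as_unit_counts <- function(x, candidates) {
  if (is.data.frame(x)) {
    col <- intersect(candidates, names(x))
    if (!length(col)) col <- setdiff(names(x), "unit_id")[1]
    if (!"unit_id" %in% names(x)) stop("data.frame input needs a `unit_id` column")
    setNames(as.numeric(x[[col[1]]]), x$unit_id)
  } else {
    if (is.null(names(x))) stop("vector input must be named by unit id")
    x
  }
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s: RMSE %.2f, %%RMSE %.2f, MAE %.2f over %d units\n",
              x$label, x$rmse, x$pct_rmse, x$mae, x$n_units))
  invisible(x)
}

#' Paired model comparison
#'
#' Element-wise differences between two accuracy reports, reported as
#' `a - b`. With the reference model first (e.g. without the event
#' covariate) and the augmented model second, positive differences mean
#' the added covariate improved the map.
#'
#' @param report_a,report_b `accuracy_report`s (a = reference/"without",
#'   b = augmented/"with").
#' @return object of class `comparison_report`: `report_a`, `report_b`,
#'   and `diff` (named: `rmse`, `pct_rmse`, `mae`).
#' @export
compare_accuracy <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "accuracy_report"),
            inherits(report_b, "accuracy_report"))
  structure(list(
    report_a = report_a, report_b = report_b,
    diff = c(rmse = report_a$rmse - report_b$rmse,
             pct_rmse = report_a$pct_rmse - report_b$pct_rmse,
             mae = report_a$mae - report_b$mae)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  df <- comparison_table(x)
  cat("<comparison_report>\n")
  print(format(df, digits = 6), row.names = FALSE)
  invisible(x)
}

#' Comparison report as a three-row table
#'
#' One row per model plus a difference row (`a - b`) — the standard shape
#' for publishing a with/without covariate accuracy comparison.
#'
#' @param comp a `comparison_report`.
#' @return data.frame with columns `model`, `rmse`, `pct_rmse`, `mae`.
#' @export
comparison_table <- function(comp) {
  a <- comp$report_a; b <- comp$report_b
  data.frame(
    model = c(a$label, b$label,
              sprintf("Difference (%s - %s)", a$label, b$label)),
    rmse = c(a$rmse, b$rmse, comp$diff["rmse"]),
    pct_rmse = c(a$pct_rmse, b$pct_rmse, comp$diff["pct_rmse"]),
    mae = c(a$mae, b$mae, comp$diff["mae"])
  )
}

#' Write a comparison report as CSV
#'
#' @param comp a `comparison_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comp, path) {
  utils::write.csv(comparison_table(comp), path, row.names = FALSE)
  invisible(path)
}

#' Average spatial resolution of a census geography
#'
#' `sqrt(total area / number of units)` in km — the side of the square
#' with the mean unit area, a broad summary of how fine a census geography
#' is.
#'
#' @param total_area_km2 total surface area in square kilometres, > 0.
#' @param n_units number of administrative units, > 0.
#' @return ASR in km.
#' @examples
#' asr(3364560.063, 6463)   # ~22.8 km, a coarse national level
#' asr(3362579.043, 79618)  # ~6.50 km, its fine counterpart
#' @export
asr <- function(total_area_km2, n_units) {
  if (total_area_km2 <= 0 || n_units <= 0) {
    stop("area and unit count must both be > 0")
  }
  sqrt(total_area_km2 / n_units)
}

#' Per-pixel difference map between two population grids
#'
#' `a - b` on identical lattices, nodata where either input is nodata.
#' When both grids conserve the same census, the difference sums to ~0.
#'
#' @param pop_a,pop_b `raster_grid`s on the same descriptor.
#' @return a `raster_grid`.
#' @export
difference_map <- function(pop_a, pop_b) {
  stopifnot_same_grid(pop_a, pop_b, "population grids")
  raster_grid(pop_a$values - pop_b$values, pop_a$origin, pop_a$cell_size)
}

#' Per-unit signed error map
#'
#' Renders predicted-minus-observed counts of (typically fine) validation
#' units as a unit-valued raster: every pixel of a unit carries that unit's
#' signed error. Also returns the error table.
#'
#' @param pred per-unit predicted counts (see [accuracy()] input forms).
#' @param obs per-unit observed counts.
#' @param admin_fine the validation `admin_layer`.
#' @return list with `raster` (a `raster_grid`) and `errors` (data.frame
#'   `unit_id`, `error`).
#' @export
unit_error_map <- function(pred, obs, admin_fine) {
  pv <- as_unit_counts(pred, c("pred_count", "count"))
  ov <- as_unit_counts(obs, c("pop_count", "obs_count", "count"))
  common <- intersect(names(pv), names(ov))
  err <- setNames(pv[common] - ov[common], common)
  m <- as.vector(admin_fine$membership)
  out <- rep(NA_real_, length(m))
  idx <- match(as.character(m), names(err))
  out[!is.na(idx)] <- err[idx[!is.na(idx)]]
  list(
    raster = raster_grid(matrix(out, admin_fine$grid$shape[1],
                                admin_fine$grid$shape[2]),
                         admin_fine$grid$origin, admin_fine$grid$cell_size),
    errors = data.frame(unit_id = as.integer(common), error = as.numeric(err))
  )
}
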
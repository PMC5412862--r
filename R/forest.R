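#' Zonal covariate summaries per census unit
#'
#' Builds the training table: one row per admin unit with the mean of each
#' stack layer over the unit's pixels (nodata pixels excluded per layer),
#' the unit's area, census count and population density (persons/km^2).
#' Units with no valid pixel in some layer are dropped with a warning.
#'
#' @param stack a `covariate_stack` on the admin layer's grid.
#' @param admin an `admin_layer` with `pop_count` set.
#' @return data.frame of class `zonal_table`: `unit_id`, `area_km2`,
#'   `pop_count`, `density`, then one column per covariate layer.
#' @export
zonal_summarize <- function(stack, admin) {
  if (nrow(admin$units) == 0L) stop("empty admin layer")
  stopifnot_same_grid(stack$grid, admin$grid, "stack and admin layer")
  if (any(is.na(admin$units$pop_count))) {
    stop("admin layer has no census counts attached")
  }
  m <- as.vector(admin$membership)
  ids <- admin$units$unit_id
  tab <- data.frame(unit_id = ids,
                    area_km2 = admin$units$area_km2,
                    pop_count = admin$units$pop_count)
  tab$density <- tab$pop_count / tab$area_km2
  for (nm in names(stack$layers)) {
    v <- as.vector(stack$layers[[nm]]$values)
    keep <- !is.na(m) & !is.na(v)
    s <- rowsum(cbind(v[keep], 1), m[keep])
    mu <- setNames(rep(NA_real_, length(ids)), ids)
    mu[rownames(s)] <- s[, 1] / s[, 2]
    tab[[nm]] <- as.numeric(mu[as.character(ids)])
  }
  covcols <- names(stack$layers)
  incomplete <- !stats::complete.cases(tab[covcols])
  if (any(incomplete)) {
    warning(sum(incomplete), " unit(s) dropped: no valid pixels in some layer")
    tab <- tab[!incomplete, , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("zonal_table", "data.frame")
  attr(tab, "covariates") <- covcols
  tab
}

#' Fit the population-density random forest
#'
#' Regresses (optionally log-transformed) census-unit population density on
#' the zonal covariate means with an unpruned regression forest. Out-of-bag
#' error and permutation importances are computed here, from the ensemble's
#' per-tree predictions and inbag counts: a unit's OOB prediction averages
#' the trees that did not sample it, OOB variance explained is
#' `1 - OOB MSE / Var(response)`, and a covariate's importance is the
#' increase in OOB mean squared error when that covariate's column is
#' randomly permuted and the OOB predictions recomputed. A constant
#' covariate is retained and gets importance 0.
#'
#' @param table a `zonal_table` (or data.frame with `density` plus
#'   covariate columns).
#' @param covariates character; defaults to the table's covariate columns.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate covariates per split; default one third of the
#'   covariates (regression convention), at least 1.
#' @param seed integer seed; the fit is deterministic given table + seed.
#' @param transform `"log"` (default; zero-density units are excluded from
#'   training, since log density is undefined for them) or `"identity"`.
#' @param min_node_size minimum terminal node size (default 5).
#' @return object of class `forest_fit`: `model` (ranger), `covariates`,
#'   `transform`, `oob_mse`, `oob_var_explained`, `importance` (named,
#'   increase in OOB MSE), `n_train`, `fingerprint`.
#' @export
fit_forest <- function(table, covariates = NULL, n_trees = 500, mtry = NULL,
                       seed = 1, transform = c("log", "identity"),
                       min_node_size = 5) {
  transform <- match.arg(transform)
  if (is.null(covariates)) covariates <- attr(table, "covariates")
  if (is.null(covariates)) {
    covariates <- setdiff(names(table),
                          c("unit_id", "area_km2", "pop_count", "density"))
  }
  if (length(covariates) < 1L) stop("need at least one covariate")
  df <- as.data.frame(table)[, c("density", covariates)]
  if (transform == "log") {
    zero <- df$density <= 0
    if (any(zero)) df <- df[!zero, , drop = FALSE]
    df$density <- log(df$density)
  }
  if (nrow(df) < 10L) stop("need at least 10 training units")
  y <- df$density
  if (stats::var(y) == 0) stop("response has zero variance")
  if (is.null(mtry)) mtry <- max(1L, floor(length(covariates) / 3))

  rf <- ranger::ranger(
    dependent.variable.name = "density", data = df,
    num.trees = n_trees, mtry = mtry, min.node.size = min_node_size,
    keep.inbag = TRUE, seed = seed, num.threads = 1
  )
  inbag <- simplify2array(rf$inbag.counts)        # n x trees
  oob <- inbag == 0
  newx <- df[, covariates, drop = FALSE]
  pred_all <- stats::predict(rf, data = newx, predict.all = TRUE,
                             num.threads = 1)$predictions
  oob_mean <- function(p) rowSums(p * oob) / pmax(rowSums(oob), 1)
  oob_pred <- oob_mean(pred_all)
  has_oob <- rowSums(oob) > 0
  oob_mse <- mean((oob_pred[has_oob] - y[has_oob])^2)
  var_y <- mean((y - mean(y))^2)
  oob_var_explained <- 1 - oob_mse / var_y

  importance <- setNames(numeric(length(covariates)), covariates)
  for (j in seq_along(covariates)) {
    xj <- covariates[j]
    if (length(unique(newx[[xj]])) == 1L) next  # permuting a constant is a no-op
    set.seed(seed + j)
    perm <- newx
    perm[[xj]] <- perm[[xj]][sample.int(nrow(perm))]
    pj <- stats::predict(rf, data = perm, predict.all = TRUE,
                         num.threads = 1)$predictions
    mse_j <- mean((oob_mean(pj)[has_oob] - y[has_oob])^2)
    importance[xj] <- mse_j - oob_mse
  }

  structure(list(model = rf, covariates = covariates, transform = transform,
                 oob_mse = oob_mse, oob_var_explained = oob_var_explained,
                 importance = importance, n_train = nrow(df),
                 fingerprint = c(n = nrow(df), p = length(covariates),
                                 y_sum = round(sum(y), 9))),
            class = "forest_fit")
}

#' @export
print.forest_fit <- function(x, ...) {
  cat(sprintf("<forest_fit> %d trees on %d units, %d covariates; OOB var explained %.3f\n",
              x$model$num.trees, x$n_train, length(x$covariates),
              x$oob_var_explained))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("importance (increase in OOB MSE):\n")
  for (nm in names(imp)) cat(sprintf("  %-12s %.5f\n", nm, imp[nm]))
  invisible(x)
}

#' Predict the per-pixel density weighting layer
#'
#' Applies the fitted forest to every pixel of the covariate stack and
#' back-transforms to persons/km^2 (exp under the log transform). A pixel
#' with nodata in any training covariate is nodata in the output.
#'
#' @param fit a `forest_fit`.
#' @param stack a `covariate_stack` whose layers are a superset of the
#'   training covariates.
#' @return a `raster_grid` weight layer (all finite values >= 0).
#' @export
predict_weights <- function(fit, stack) {
  missing_layers <- setdiff(fit$covariates, names(stack$layers))
  if (length(missing_layers)) {
    stop("stack is missing covariate layer(s): ",
         paste(missing_layers, collapse = ", "))
  }
  shape <- stack$grid$shape
  X <- as.data.frame(lapply(stack$layers[fit$covariates],
                            function(l) as.vector(l$values)))
  names(X) <- fit$covariates
  valid <- stats::complete.cases(X)
  out <- rep(NA_real_, prod(shape))
  if (any(valid)) {
    p <- stats::predict(fit$model, data = X[valid, , drop = FALSE],
                        num.threads = 1)$predictions
    out[valid] <- if (fit$transform == "log") exp(p) else pmax(p, 0)
  }
  raster_grid(matrix(out, shape[1], shape[2]),
              stack$grid$origin, stack$grid$cell_size)
}

#' Tabular prediction from a forest fit
#'
#' Predicts back-transformed density for rows of a covariate table; the
#' raster path in [predict_weights()] agrees with this on any pixel whose
#' covariate vector equals a table row.
#'
#' @param fit a `forest_fit`.
#' @param newdata data.frame containing the training covariates.
#' @return numeric vector of densities (persons/km^2).
#' @export
predict_density <- function(fit, newdata) {
  p <- stats::predict(fit$model,
                      data = newdata[, fit$covariates, drop = FALSE],
                      num.threads = 1)$predictions
  if (fit$transform == "log") exp(p) else pmax(p, 0)
}

#' Dasymetric redistribution of census counts
#'
#' Allocates each unit's census count over its pixels proportionally to the
#' weight layer: `pixel_pop = count * weight / sum(unit weights)`, with
#' nodata weights treated as 0. A unit whose weights sum to 0 (or are all
#' nodata) falls back to uniform allocation over its pixels; fallbacks are
#' reported via the `n_fallback_units` attribute. Per-unit sums equal the
#' census counts up to floating-point rounding, and the redistribution is
#' invariant to rescaling a unit's weights by any positive constant.
#'
#' @param weights a `raster_grid` of non-negative weights.
#' @param admin an `admin_layer` with `pop_count` set.
#' @return a `raster_grid` of persons per pixel (`population_grid`
#'   semantics); `NA` outside the admin region.
#' @export
dasymetric_redistribute <- function(weights, admin) {
  stopifnot_same_grid(grid_descriptor(weights), admin$grid,
                      "weight layer and admin layer")
  if (any(is.na(admin$units$pop_count))) {
    stop("admin layer has no census counts attached")
  }
  if (any(admin$units$n_pixels == 0)) {
    stop("admin layer contains units with zero pixels")
  }
  m <- as.vector(admin$membership)
  w <- as.vector(weights$values)
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("weights must be non-negative")
  member <- !is.na(m)

  wsum <- rowsum(w[member], m[member])
  npix <- rowsum(rep(1, sum(member)), m[member])
  ids <- rownames(wsum)
  counts <- setNames(admin$units$pop_count, admin$units$unit_id)[ids]
  fallback <- wsum[, 1] <= 0
  scale <- ifelse(fallback, 0, counts / ifelse(wsum[, 1] > 0, wsum[, 1], 1))
  unif <- ifelse(fallback, counts / npix[, 1], 0)

  idx <- match(m[member], as.integer(ids))
  out <- rep(NA_real_, length(m))
  out[member] <- w[member] * scale[idx] + unif[idx]
  res <- raster_grid(matrix(out, admin$grid$shape[1], admin$grid$shape[2]),
                     admin$grid$origin, admin$grid$cell_size)
  attr(res, "n_fallback_units") <- sum(fallback)
  res
}
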
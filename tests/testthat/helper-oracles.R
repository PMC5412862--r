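# Small study region used across tests: big enough for the hierarchy and
# forest preconditions, small enough that brute-force oracles are instant.
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, grid_shape = c(32, 32), n_coarse_units = 6,
               fine_per_coarse = 3, pop_total = 5e4, tweet_rate = 0.02)
  override <- list(...)
  args[names(override)] <- override
  do.call(landscape_config, args)
}

# Brute-force floor binning: one event at a time, literal arithmetic.
bf_aggregate_points <- function(events, cell_size, extent) {
  ix0 <- floor(extent["xmin"] / cell_size)
  ix1 <- ceiling(extent["xmax"] / cell_size) - 1
  iy0 <- floor(extent["ymin"] / cell_size)
  iy1 <- ceiling(extent["ymax"] / cell_size) - 1
  counts <- matrix(0, iy1 - iy0 + 1, ix1 - ix0 + 1)
  for (i in seq_len(nrow(events))) {
    ix <- floor(events$lon[i] / cell_size)
    iy <- floor(events$lat[i] / cell_size)
    if (ix >= ix0 && ix <= ix1 && iy >= iy0 && iy <= iy1) {
      r <- iy1 - iy + 1
      c <- ix - ix0 + 1
      counts[r, c] <- counts[r, c] + 1
    }
  }
  counts
}

# Brute-force nearest class-pixel distance (pixel centers, planar).
bf_distance <- function(class_mat, cell_size) {
  idx <- which(class_mat == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(class_mat), ncol(class_mat))
  for (r in seq_len(nrow(class_mat))) {
    for (c in seq_len(ncol(class_mat))) {
      if (is.na(class_mat[r, c])) next
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2)) * cell_size
    }
  }
  out
}

# Brute-force zonal mean accumulation, pixel by pixel.
bf_zonal_mean <- function(values, membership) {
  sums <- list(); ns <- list()
  for (i in seq_along(values)) {
    m <- membership[i]; v <- values[i]
    if (is.na(m) || is.na(v)) next
    key <- as.character(m)
    sums[[key]] <- (sums[[key]] %||% 0) + v
    ns[[key]] <- (ns[[key]] %||% 0) + 1
  }
  keys <- sort(as.integer(names(sums)))
  setNames(vapply(as.character(keys), function(k) sums[[k]] / ns[[k]],
                  numeric(1)), keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_accuracy <- function(pred, obs) {
  stopifnot(identical(names(pred), names(obs)))
  e <- pred - obs
  list(rmse = sqrt(sum(e^2) / length(e)),
       mae = sum(abs(e)) / length(e),
       pct_rmse = 100 * sqrt(sum(e^2) / length(e)) / (sum(obs) / length(obs)))
}
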
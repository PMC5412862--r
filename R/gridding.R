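#' Read / write point-event tables
#'
#' Events are exchanged as CSV with header `lon,lat[,timestamp]`. On read,
#' rows with missing or out-of-range coordinates (|lon| > 180, |lat| > 90)
#' are rejected and their count attached as the `n_malformed` attribute.
#'
#' @param path CSV file path.
#' @param events data.frame with `lon` and `lat` columns.
#' @return `read_events_csv`: data.frame of clean events;
#'   `write_events_csv`: `path` invisibly.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(ev))) {
    stop("events CSV must have `lon` and `lat` columns")
  }
  ev$lon <- suppressWarnings(as.numeric(ev$lon))
  ev$lat <- suppressWarnings(as.numeric(ev$lat))
  ok <- is.finite(ev$lon) & is.finite(ev$lat) &
    abs(ev$lon) <= 180 & abs(ev$lat) <= 90
  out <- ev[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  extra <- setdiff(names(events), c("lon", "lat"))
  writeLines(paste(c("lon", "lat", extra), collapse = ","), con)
  if (nrow(events)) {
    body <- sprintf("%.8f,%.8f", events$lon, events$lat)
    for (nm in extra) body <- paste(body, events[[nm]], sep = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' Aggregate point events to a count grid by floor binning
#'
#' Assigns every event to the cell whose origin is
#' `floor(coordinate / cell_size) * cell_size` on each axis — floor toward
#' minus infinity, so at southern latitudes an event at -6.2088 falls in
#' the cell with origin -6.209, not -6.208 (truncation toward zero would
#' differ by one cell south of the equator). Cells are half-open
#' `[origin, origin + cell_size)`. The grid covers the requested extent
#' snapped outward to the cell lattice; events outside it are dropped and
#' counted.
#'
#' @param events data.frame with `lon`, `lat` (rows with non-finite or
#'   out-of-range coordinates are rejected and counted).
#' @param cell_size cell edge in degrees, > 0.
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)`.
#' @return a `raster_grid` of non-negative integer counts with attributes
#'   `n_dropped` (in-range coordinates outside the extent) and
#'   `n_malformed` (rejected rows). The grid sum equals the number of
#'   in-extent events.
#' @examples
#' ev <- data.frame(lon = c(106.8456, 106.8456), lat = c(-6.2088, -6.2088))
#' g <- aggregate_points(ev, 0.001, c(xmin = 106.8, xmax = 106.9,
#'                                    ymin = -6.3, ymax = -6.1))
#' sum(g$values)  # 2
#' @export
aggregate_points <- function(events, cell_size, extent) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  extent <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (any(is.na(extent)) || extent["xmax"] <= extent["xmin"] ||
      extent["ymax"] <= extent["ymin"]) {
    stop("extent must be a non-degenerate named bounding box")
  }
  ok <- is.finite(events$lon) & is.finite(events$lat) &
    abs(events$lon) <= 180 & abs(events$lat) <= 90
  n_malformed <- sum(!ok)
  lon <- events$lon[ok]; lat <- events$lat[ok]

  # snap the extent outward to the absolute cell lattice
  ix0 <- floor(extent["xmin"] / cell_size)
  ix1 <- ceiling(extent["xmax"] / cell_size) - 1  # last cell origin index
  iy0 <- floor(extent["ymin"] / cell_size)
  iy1 <- ceiling(extent["ymax"] / cell_size) - 1
  ncol_ <- as.integer(ix1 - ix0 + 1)
  nrow_ <- as.integer(iy1 - iy0 + 1)

  ix <- floor(lon / cell_size)
  iy <- floor(lat / cell_size)
  inside <- ix >= ix0 & ix <= ix1 & iy >= iy0 & iy <= iy1
  n_dropped <- sum(!inside)

  counts <- matrix(0, nrow_, ncol_)
  if (any(inside)) {
    col <- as.integer(ix[inside] - ix0) + 1L
    row <- as.integer(iy1 - iy[inside]) + 1L  # row 1 = northernmost cell
    counts[] <- tabulate(row + (col - 1L) * nrow_, nbins = nrow_ * ncol_)
  }
  out <- raster_grid(counts,
                     origin = c(ix0 * cell_size, (iy1 + 1) * cell_size),
                     cell_size = cell_size)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_malformed") <- n_malformed
  out
}
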
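#' Georeferenced raster lattice
#'
#' A `raster_grid` is a 2-D lattice of values on an unprojected geographic
#' grid: a numeric matrix (`values[row, col]`, row 1 at the northern edge)
#' plus an upper-left corner, a square cell size in decimal degrees, and an
#' `NA`-based nodata convention. It is the common currency for covariates,
#' weighting layers and population-per-pixel surfaces.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param origin numeric length-2, `c(lon, lat)` of the grid's upper-left
#'   corner (the corner of cell `[1, 1]`, not its center).
#' @param cell_size cell edge length in degrees; cells are square.
#' @return An object of class `raster_grid`.
#' @examples
#' rg <- raster_grid(matrix(1:12, 3, 4), origin = c(106, -6), cell_size = 0.01)
#' grid_extent(rg)
#' @export
raster_grid <- function(values, origin, cell_size) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be c(lon, lat) of the upper-left corner")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf(
    "<raster_grid> %d x %d cells of %g deg; extent lon [%g, %g] lat [%g, %g]; %d nodata\n",
    nrow(x$values), ncol(x$values), x$cell_size,
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"],
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Grid descriptor and extent helpers
#'
#' `grid_descriptor` strips the values from a raster, leaving the geometry
#' (origin, cell size, shape) that other layers must share. `grid_extent`
#' returns the bounding box, `cell_centers` the lon/lat of every cell center
#' in matrix order (column-major over `values`).
#'
#' @param x a `raster_grid` (or a bare descriptor for `grid_extent`).
#' @return `grid_descriptor`: a list with `origin`, `cell_size`, `shape`;
#'   `grid_extent`: named numeric `xmin, xmax, ymin, ymax`;
#'   `cell_centers`: a list with vectors `lon`, `lat`.
#' @export
grid_descriptor <- function(x) {
  list(origin = x$origin, cell_size = x$cell_size, shape = dim(x$values))
}

#' @rdname grid_descriptor
#' @export
grid_extent <- function(x) {
  shape <- if (is.null(x$shape)) dim(x$values) else x$shape
  c(xmin = x$origin[1], xmax = x$origin[1] + shape[2] * x$cell_size,
    ymin = x$origin[2] - shape[1] * x$cell_size, ymax = x$origin[2])
}

#' @rdname grid_descriptor
#' @export
cell_centers <- function(x) {
  shape <- if (is.null(x$shape)) dim(x$values) else x$shape
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  list(lon = x$origin[1] + (as.vector(cols) - 0.5) * x$cell_size,
       lat = x$origin[2] - (as.vector(rows) - 0.5) * x$cell_size)
}

#' Test whether two rasters share a grid
#'
#' Geometry comparison with a small absolute tolerance on origin and cell
#' size (degrees); shapes must match exactly.
#'
#' @param a,b `raster_grid`s or descriptors.
#' @param tol tolerance in degrees.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  da <- if (inherits(a, "raster_grid")) grid_descriptor(a) else a
  db <- if (inherits(b, "raster_grid")) grid_descriptor(b) else b
  all(abs(da$origin - db$origin) <= tol) &&
    abs(da$cell_size - db$cell_size) <= tol &&
    identical(as.integer(da$shape), as.integer(db$shape))
}

stopifnot_same_grid <- function(a, b, what = "layers") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

#' Locate points on a raster lattice
#'
#' Maps lon/lat coordinates to (row, col) indices under the half-open cell
#' convention of floor binning: a cell owns `[origin, origin + cell_size)`
#' on both axes, where the y-origin is the cell's southern edge. Points
#' outside the extent get `NA` indices.
#'
#' @param x a `raster_grid` or descriptor.
#' @param lon,lat numeric coordinate vectors.
#' @return data.frame with columns `row`, `col`, `inside`.
#' @export
locate_cells <- function(x, lon, lat) {
  shape <- if (is.null(x$shape)) dim(x$values) else x$shape
  col <- floor((lon - x$origin[1]) / x$cell_size) + 1
  # southern edge inclusive, northern exclusive: ceiling, so a point exactly
  # on an internal horizontal edge falls in the row whose south edge it is
  row <- ceiling((x$origin[2] - lat) / x$cell_size)
  inside <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= shape[2] & row >= 1 & row <= shape[1]
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange. The header stores the
#' lower-left corner, cell size and nodata sentinel; rows are written north
#' to south. Values round-trip through `%.12g` formatting, so origin and
#' cell size are preserved well below 1e-9 degrees.
#'
#' @param x a `raster_grid`.
#' @param path file path (`.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `write_raster_asc`: `path` invisibly. `read_raster_asc`: a
#'   `raster_grid`.
#' @export
write_raster_asc <- function(x, path, nodata = -9999) {
  v <- x$values
  shape <- dim(v)
  ext <- grid_extent(x)
  hdr <- c(
    sprintf("ncols %d", shape[2]),
    sprintf("nrows %d", shape[1]),
    sprintf("xllcorner %.12g", ext["xmin"]),
    sprintf("yllcorner %.12g", ext["ymin"]),
    sprintf("cellsize %.12g", x$cell_size),
    sprintf("NODATA_value %.12g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (length(ln) != 1L) stop(sprintf("malformed ASCII grid header: %s", key))
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nd <- val("NODATA_value")
  body <- lines[-(1:6)]
  if (length(body) != nrows) stop("ASCII grid body row count mismatch")
  v <- t(vapply(body, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(ncols), USE.NAMES = FALSE))
  v <- matrix(v, nrows, ncols)
  v[v == nd] <- NA_real_
  raster_grid(v, origin = c(xll, yll + nrows * cs), cell_size = cs)
}

#' Align a raster to a target lattice
#'
#' Moves values from one lattice to another under two regimes. When the
#' target cell is at least as large as the source cell, each source cell's
#' value is added to the target cell containing the source cell center
#' (sum-preserving block aggregation, the right rule for counts). When the
#' target is finer, each target cell takes the value of the source cell
#' containing the target cell center (nearest-value refinement).
#'
#' @param x source `raster_grid` (counts or values).
#' @param target a `raster_grid` or descriptor giving the output lattice.
#' @param method `"auto"` (default: aggregate when target is coarser or
#'   equal, nearest when finer), `"sum"`, or `"nearest"`.
#' @return a `raster_grid` on the target lattice. Target cells receiving no
#'   source cell (aggregation) are 0; target cells whose center falls
#'   outside the source (refinement) are `NA`.
#' @export
align_to_grid <- function(x, target, method = c("auto", "sum", "nearest")) {
  method <- match.arg(method)
  tgt <- if (inherits(target, "raster_grid")) grid_descriptor(target) else target
  src <- grid_descriptor(x)
  if (same_grid(src, tgt)) return(raster_grid(x$values, tgt$origin, tgt$cell_size))
  ex_s <- grid_extent(src); ex_t <- grid_extent(tgt)
  if (ex_s["xmin"] >= ex_t["xmax"] || ex_t["xmin"] >= ex_s["xmax"] ||
      ex_s["ymin"] >= ex_t["ymax"] || ex_t["ymin"] >= ex_s["ymax"]) {
    stop("source and target extents are disjoint")
  }
  if (method == "auto") {
    method <- if (tgt$cell_size >= src$cell_size - 1e-12) "sum" else "nearest"
  }
  out <- matrix(NA_real_, tgt$shape[1], tgt$shape[2])
  if (method == "sum") {
    out[] <- 0
    ctr <- cell_centers(x)
    loc <- locate_cells(tgt, ctr$lon, ctr$lat)
    keep <- loc$inside & !is.na(as.vector(x$values))
    if (any(keep)) {
      idx <- (loc$col[keep] - 1L) * tgt$shape[1] + loc$row[keep]
      s <- rowsum(as.vector(x$values)[keep], idx)
      out[as.integer(rownames(s))] <- s[, 1]
    }
  } else {
    ctr <- cell_centers(tgt)
    loc <- locate_cells(src, ctr$lon, ctr$lat)
    src_idx <- (loc$col - 1L) * src$shape[1] + loc$row
    vals <- rep(NA_real_, length(src_idx))
    vals[loc$inside] <- as.vector(x$values)[src_idx[loc$inside]]
    out[] <- vals
  }
  raster_grid(out, tgt$origin, tgt$cell_size)
}
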
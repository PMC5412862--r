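#' Administrative census layer on the pixel lattice
#'
#' An `admin_layer` represents one level of a census geography as a pixel
#' partition: a membership matrix (unit id per pixel, `NA` outside the
#' region) aligned on a raster descriptor, plus a unit table with id,
#' optional parent id, pixel count, area and population count. Working on
#' pixel membership rather than polygon geometry makes zonal arithmetic
#' (and hence every conservation invariant) exact; polygon output is
#' derived from membership at export time.
#'
#' @param units data.frame with columns `unit_id`, `parent_id` (`NA` at the
#'   coarse level), `n_pixels`, `area_km2`, `pop_count` (`NA` until census
#'   counts are attached).
#' @param membership integer matrix of unit ids, same shape as the grid.
#' @param grid a grid descriptor (see [grid_descriptor()]).
#' @param level character label, e.g. `"coarse"` or `"fine"`.
#' @return An object of class `admin_layer`.
#' @export
admin_layer <- function(units, membership, grid, level = "units") {
  need <- c("unit_id", "parent_id", "n_pixels", "area_km2", "pop_count")
  if (!all(need %in% names(units))) {
    stop("`units` must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(units$unit_id)) stop("unit ids must be unique")
  if (!identical(dim(membership), as.integer(grid$shape))) {
    stop("membership matrix does not match the grid shape")
  }
  seen <- sort(unique(membership[!is.na(membership)]))
  if (!all(seen %in% units$unit_id)) {
    stop("membership contains unit ids missing from the unit table")
  }
  structure(list(units = units, membership = membership,
                 grid = grid, level = level),
            class = "admin_layer")
}

#' @export
print.admin_layer <- function(x, ...) {
  cat(sprintf("<admin_layer> level '%s': %d units, %d member pixels, total pop %s\n",
              x$level, nrow(x$units), sum(!is.na(x$membership)),
              if (all(is.na(x$units$pop_count))) "unset"
              else format(sum(x$units$pop_count))))
  invisible(x)
}

#' Kilometres per degree used for planar areas
#'
#' Unit areas are computed planarly as (cell_size x 111.32 km)^2 per pixel,
#' the small-region approximation on an unprojected grid.
#' @keywords internal
KM_PER_DEGREE <- 111.32

pixel_area_km2 <- function(cell_size) (cell_size * KM_PER_DEGREE)^2

#' Attach census counts from a truth grid
#'
#' Sets each unit's `pop_count` to the zonal sum of a per-pixel population
#' raster over the unit's member pixels. Because fine units partition
#' coarse units pixel-by-pixel and pixel populations are integers, the
#' nested-sum invariant (fine counts within a parent sum to the parent
#' count) holds exactly.
#'
#' @param true_population a `raster_grid` of persons per pixel.
#' @param admin_coarse,admin_fine `admin_layer`s on the same grid.
#' @return list with elements `coarse` and `fine`: the layers with
#'   `pop_count` filled in.
#' @export
census_from_truth <- function(true_population, admin_coarse, admin_fine) {
  fill <- function(admin) {
    stopifnot_same_grid(grid_descriptor(true_population), admin$grid,
                        "truth grid and admin layer")
    v <- as.vector(true_population$values)
    m <- as.vector(admin$membership)
    keep <- !is.na(m) & !is.na(v)
    s <- rowsum(v[keep], m[keep])
    counts <- setNames(rep(0, nrow(admin$units)), admin$units$unit_id)
    counts[rownames(s)] <- s[, 1]
    admin$units$pop_count <- as.numeric(counts[as.character(admin$units$unit_id)])
    admin
  }
  list(coarse = fill(admin_coarse), fine = fill(admin_fine))
}

#' Export an admin layer as GeoJSON
#'
#' Writes one MultiPolygon feature per unit, with properties `unit_id`,
#' `parent_id` (empty string at the coarse level), `pop_count` and
#' `area_km2`. Geometry is derived from pixel membership as row-runs of
#' pixel rectangles; adjacent runs are not dissolved, which keeps the
#' writer simple and the geometry exact.
#'
#' @param admin an `admin_layer`.
#' @param path output file path (`.geojson`).
#' @return `path`, invisibly.
#' @export
write_admin_geojson <- function(admin, path) {
  g <- admin$grid
  cs <- g$cell_size
  xmin <- g$origin[1]; ymax <- g$origin[2]
  features <- lapply(seq_len(nrow(admin$units)), function(i) {
    uid <- admin$units$unit_id[i]
    polys <- list()
    for (r in seq_len(g$shape[1])) {
      inrow <- which(!is.na(admin$membership[r, ]) & admin$membership[r, ] == uid)
      if (!length(inrow)) next
      breaks <- c(0, which(diff(inrow) != 1), length(inrow))
      for (k in seq_len(length(breaks) - 1)) {
        c0 <- inrow[breaks[k] + 1]; c1 <- inrow[breaks[k + 1]]
        x0 <- xmin + (c0 - 1) * cs; x1 <- xmin + c1 * cs
        y1 <- ymax - (r - 1) * cs; y0 <- ymax - r * cs
        ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
        polys[[length(polys) + 1]] <- list(ring)
      }
    }
    list(
      type = "Feature",
      properties = list(
        unit_id = uid,
        parent_id = if (is.na(admin$units$parent_id[i])) ""
                    else admin$units$parent_id[i],
        pop_count = admin$units$pop_count[i],
        area_km2 = admin$units$area_km2[i]
      ),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read unit attributes back from GeoJSON
#'
#' Returns the property table of a layer written by
#' [write_admin_geojson()]; geometry is not reconstructed into pixel
#' membership (membership is the in-memory source of truth).
#'
#' @param path a GeoJSON file.
#' @return data.frame of unit properties.
#' @export
read_admin_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- lapply(obj$features, function(f) {
    p <- f$properties
    data.frame(
      unit_id = as.integer(p$unit_id),
      parent_id = if (is.null(p$parent_id) || identical(p$parent_id, ""))
        NA_integer_ else as.integer(p$parent_id),
      pop_count = if (is.null(p$pop_count)) NA_real_ else as.numeric(p$pop_count),
      area_km2 = as.numeric(p$area_km2)
    )
  })
  do.call(rbind, rows)
}
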
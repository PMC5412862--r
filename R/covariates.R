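#' Binary class-membership raster
#'
#' The `_cls` convention: 1 where the thematic layer equals `class_value`,
#' 0 elsewhere, nodata propagated. If the class value is absent a warning
#' is raised and an all-zero raster returned.
#'
#' @param layer a `raster_grid`.
#' @param class_value the thematic value defining the class.
#' @return a binary `raster_grid`.
#' @export
class_raster <- function(layer, class_value) {
  v <- layer$values
  out <- (v == class_value) * 1
  out[is.na(v)] <- NA_real_
  if (!any(out == 1, na.rm = TRUE)) {
    warning("class value ", class_value, " absent: all-zero class raster")
  }
  raster_grid(out, layer$origin, layer$cell_size)
}

# Felzenszwalb & Huttenlocher 1-D squared distance transform of a sampled
# function f; BIG stands in for +Inf to keep the parabola intersections
# finite.
dt1d_sq <- function(f, BIG = 1e15) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -BIG; z[2] <- BIG
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- BIG
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance-to-class raster
#'
#' The `_dst` convention: per-pixel planar Euclidean distance from the
#' pixel center to the nearest class-1 pixel center, in degrees (cell units
#' times cell size), exactly 0 on class pixels. Computed with the exact
#' two-pass parabolic distance transform, so it matches a brute-force
#' nearest-pixel search to machine precision. Nodata pixels neither anchor
#' distances nor receive one.
#'
#' @param class_layer a binary `raster_grid` (values in \{0, 1, NA\}).
#' @return a `raster_grid` of distances (degrees).
#' @export
distance_raster <- function(class_layer) {
  v <- class_layer$values
  bad <- v[!is.na(v)]
  if (length(bad) && !all(bad %in% c(0, 1))) {
    stop("class layer must be binary")
  }
  if (!any(v == 1, na.rm = TRUE)) {
    stop("distance to an all-zero class layer is undefined")
  }
  BIG <- 1e15
  f <- matrix(BIG, nrow(v), ncol(v))
  f[!is.na(v) & v == 1] <- 0
  f <- apply(f, 2L, dt1d_sq)               # along columns (rows axis)
  f <- t(apply(f, 1L, dt1d_sq))            # along rows (cols axis)
  out <- sqrt(f) * class_layer$cell_size
  out[is.na(v)] <- NA_real_
  raster_grid(out, class_layer$origin, class_layer$cell_size)
}

#' Assemble an aligned covariate stack
#'
#' Collects named layers onto a shared grid descriptor, resampling any
#' misaligned layer by role: `"class"` and `"continuous"` layers by
#' nearest-value refinement, `"count"` layers by sum-preserving
#' aggregation (see [align_to_grid()]). Roles default from the name suffix
#' (`_cls` is class, `_dst` and everything else continuous). Layers are
#' ordered lexicographically, so assembly is deterministic and
#' order-stable regardless of input order.
#'
#' @param layers named list of `raster_grid`s; names must be unique.
#' @param descriptor target grid descriptor; defaults to the first layer's.
#' @param roles optional named character overriding a layer's role
#'   (`"class"`, `"continuous"`, `"count"`).
#' @return object of class `covariate_stack`: list with `grid` (the
#'   descriptor) and `layers` (named, lexicographic order).
#' @export
assemble_stack <- function(layers, descriptor = NULL, roles = NULL) {
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all layers must be named")
  }
  if (anyDuplicated(names(layers))) {
    stop("duplicate layer name: ",
         paste(unique(names(layers)[duplicated(names(layers))]), collapse = ", "))
  }
  if (is.null(descriptor)) descriptor <- grid_descriptor(layers[[1]])
  out <- list()
  for (nm in sort(names(layers))) {
    lyr <- layers[[nm]]
    role <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]]
            else if (grepl("_cls$", nm)) "class" else "continuous"
    if (same_grid(lyr, descriptor)) {
      aligned <- raster_grid(lyr$values, descriptor$origin, descriptor$cell_size)
    } else {
      ex_s <- grid_extent(grid_descriptor(lyr)); ex_t <- grid_extent(descriptor)
      if (ex_s["xmin"] >= ex_t["xmax"] || ex_t["xmin"] >= ex_s["xmax"] ||
          ex_s["ymin"] >= ex_t["ymax"] || ex_t["ymin"] >= ex_s["ymax"]) {
        stop("layer `", nm, "` does not overlap the stack grid")
      }
      aligned <- align_to_grid(lyr, descriptor,
                               method = if (role == "count") "sum" else "nearest")
    }
    if (role == "class") {
      u <- aligned$values[!is.na(aligned$values)]
      if (length(u) && !all(u %in% c(0, 1))) {
        stop("class layer `", nm, "` is not binary after alignment")
      }
    }
    out[[nm]] <- aligned
  }
  structure(list(grid = descriptor, layers = out), class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$shape[1], x$grid$shape[2],
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Write / read a covariate stack
#'
#' Each layer goes to `<name>.asc` (ASCII grid) next to a `manifest.yml`
#' mapping layer name to file and role, so a stack round-trips through
#' plain text.
#'
#' @param stack a `covariate_stack`.
#' @param dir directory for layers + manifest.
#' @return `write_stack`: `dir` invisibly; `read_stack`: a
#'   `covariate_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".asc")
    write_raster_asc(stack$layers[[nm]], file.path(dir, f))
    manifest[[nm]] <- list(
      path = f,
      role = if (grepl("_cls$", nm)) "class" else "continuous"
    )
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  layers <- lapply(manifest, function(m) read_raster_asc(file.path(dir, m$path)))
  roles <- vapply(manifest, function(m) m$role, character(1))
  assemble_stack(layers, roles = roles)
}
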
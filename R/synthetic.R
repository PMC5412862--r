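#' Configuration for a synthetic study region
#'
#' Bundles every knob of the synthetic landscape: grid geometry, the
#' two-level administrative hierarchy, the log-linear population model, and
#' the point-event process with its bias controls. The defaults describe a
#' desk-scale region that mirrors, qualitatively, the regime of a national
#' census-disaggregation study: a coarse training level subdivided roughly
#' 1:12 into a fine validation level, population driven by a built-up class
#' and night-time lights with elevation as an uninformative layer, and
#' point events whose intensity follows population with optional
#' transport-corridor and neighborhood-snapping biases.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param grid_shape integer `c(rows, cols)`, both >= 16.
#' @param cell_size cell edge in degrees.
#' @param origin `c(lon, lat)` of the grid's upper-left corner.
#' @param n_coarse_units number of coarse (training-level) units, >= 2.
#' @param fine_per_coarse mean subdivisions of each coarse unit, >= 2.
#' @param pop_total total population of the region, persons.
#' @param beta named log-linear coefficients linking standardized
#'   covariates to population intensity; names must be covariate names.
#' @param noise_sd standard deviation of the log-intensity noise term.
#' @param tweet_rate expected events per person (>= 0).
#' @param road_bias multiplier for event intensity on the road corridor
#'   (0 = unbiased).
#' @param snap_fraction fraction of events relocated to the nearest
#'   snapping centroid, in `[0, 1]`.
#' @param snap_centroids number of snapping centroids.
#' @param built_fraction fraction of pixels in the built class.
#' @return An object of class `landscape_config` (a validated list).
#' @examples
#' cfg <- landscape_config(seed = 1, grid_shape = c(32, 32))
#' @export
landscape_config <- function(seed,
                             grid_shape = c(96, 96),
                             cell_size = 0.01,
                             origin = c(106, -5),
                             n_coarse_units = 40,
                             fine_per_coarse = 12,
                             pop_total = 1e6,
                             beta = c(blt_cls = 0.8, lig = 0.4,
                                      roa_cls = 0.15, ele = 0),
                             noise_sd = 0.5,
                             tweet_rate = 0.05,
                             road_bias = 0,
                             snap_fraction = 0,
                             snap_centroids = 25,
                             built_fraction = 0.25) {
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- list(seed = as.integer(seed),
              grid_shape = as.integer(grid_shape), cell_size = cell_size,
              origin = as.numeric(origin),
              n_coarse_units = as.integer(n_coarse_units),
              fine_per_coarse = fine_per_coarse, pop_total = pop_total,
              beta = beta, noise_sd = noise_sd, tweet_rate = tweet_rate,
              road_bias = road_bias, snap_fraction = snap_fraction,
              snap_centroids = as.integer(snap_centroids),
              built_fraction = built_fraction)
  validate_landscape_config(cfg)
  class(cfg) <- "landscape_config"
  cfg
}

validate_landscape_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 2L || any(grid_shape < 16L)) {
      stop("grid_shape dimensions must both be >= 16")
    }
    if (cell_size <= 0) stop("cell_size must be > 0")
    if (pop_total <= 0) stop("pop_total must be > 0")
    if (n_coarse_units < 2L) stop("n_coarse_units must be >= 2")
    if (n_coarse_units > prod(grid_shape)) {
      stop("n_coarse_units exceeds the pixel count")
    }
    if (fine_per_coarse < 2) stop("fine_per_coarse must be >= 2")
    if (tweet_rate < 0) stop("tweet_rate must be >= 0")
    if (snap_fraction < 0 || snap_fraction > 1) {
      stop("snap_fraction must lie in [0, 1]")
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (built_fraction <= 0 || built_fraction >= 1) {
      stop("built_fraction must lie strictly in (0, 1)")
    }
  })
  invisible(cfg)
}

#' Read / write a landscape configuration
#'
#' Key-value YAML serialization of a [landscape_config()]; `seed` is
#' mandatory in the file.
#'
#' @param path file path.
#' @param cfg a `landscape_config`.
#' @return `read_landscape_config`: a `landscape_config`;
#'   `write_landscape_config`: `path` invisibly.
#' @export
read_landscape_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config file must set `seed`")
  if (!is.null(raw$beta)) raw$beta <- unlist(raw$beta)
  do.call(landscape_config, raw)
}

#' @rdname read_landscape_config
#' @export
write_landscape_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$beta <- as.list(out$beta)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Smooth a white-noise field with a separable Gaussian kernel, reflecting at
# the edges via kernel renormalization (convolve the mask of ones too).
smooth_field <- function(mat, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- stats::convolve(c(rep(0, half), v, rep(0, half)), rev(k),
                           type = "filter")
    wt <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), rev(k),
                          type = "filter")
    out / wt
  }
  sm <- apply(mat, 2L, pad_conv)
  t(apply(sm, 1L, pad_conv))
}

# Rasterize a polyline onto the lattice: walk each segment at sub-cell steps
# and mark every visited cell.
rasterize_polyline <- function(shape, pts) {
  m <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    n <- max(2L, ceiling(2 * max(abs(b - a))))
    rr <- round(seq(a[1], b[1], length.out = n))
    cc <- round(seq(a[2], b[2], length.out = n))
    rr <- pmin(pmax(rr, 1L), shape[1]); cc <- pmin(pmax(cc, 1L), shape[2])
    m[cbind(rr, cc)] <- 1
  }
  m
}

#' Generate synthetic covariate rasters
#'
#' Builds, deterministically from the config seed, the ancillary layers the
#' population model consumes: `blt_cls`, a binary built-up class obtained
#' by thresholding a smoothed Gaussian random field at the configured built
#' fraction; `lig`, a continuous night-time-lights analogue constructed
#' from the same latent field plus independent smooth noise (hence
#' positively associated with the built class); `ele`, a continuous
#' elevation analogue from an independent field (uninformative about
#' population by construction); and `roa_cls`, a binary road corridor
#' rasterized from a west-to-east polyline through random waypoints.
#'
#' @param config a [landscape_config()].
#' @return named list of `raster_grid`s, all on the config grid.
#' @export
generate_covariates <- function(config) {
  validate_landscape_config(config)
  shape <- config$grid_shape
  set.seed(derive_seed(config$seed, "covariates"))
  # landscape correlation length: built patches must be resolved at the
  # admin-unit scale (settlements span whole census units), otherwise unit
  # covariate means cannot carry the pixel-level contrast the weighting
  # layer needs
  sigma <- max(2, min(shape) / 8)

  latent <- smooth_field(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                         sigma)
  thr <- stats::quantile(latent, 1 - config$built_fraction)
  blt <- (latent > thr) * 1

  lig_noise <- smooth_field(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                            sigma)
  lig <- pmax(0, scale01(latent) * 60 + scale01(lig_noise) * 15)

  ele <- scale01(smooth_field(matrix(stats::rnorm(prod(shape)),
                                     shape[1], shape[2]), sigma * 1.5)) * 1500

  n_way <- 4L
  way_rows <- round(stats::runif(n_way + 2, 1, shape[1]))
  way_cols <- round(seq(1, shape[2], length.out = n_way + 2))
  roa <- rasterize_polyline(shape, cbind(way_rows, way_cols))

  grid <- function(v) raster_grid(matrix(v, shape[1], shape[2]),
                                  config$origin, config$cell_size)
  list(blt_cls = grid(blt), lig = grid(lig), ele = grid(ele),
       roa_cls = grid(roa))
}

scale01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] == 0) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Generate a nested two-level administrative hierarchy
#'
#' Coarse units are the lattice Voronoi cells of `n_coarse_units` seed
#' pixels (nearest-seed assignment, ties to the lowest unit id), so they
#' partition the region into contiguous blocks. Each coarse unit is then
#' subdivided the same way by fine seeds drawn from its own pixels; the
#' number of fine seeds per coarse unit is Poisson around
#' `fine_per_coarse`, floored at 2. Population counts are left unset.
#'
#' @param config a [landscape_config()].
#' @return list with `admin_layer`s `coarse` and `fine`; fine units carry
#'   their coarse parent's id in `parent_id`.
#' @export
generate_admin_hierarchy <- function(config) {
  validate_landscape_config(config)
  shape <- config$grid_shape
  npix <- prod(shape)
  set.seed(derive_seed(config$seed, "admin"))

  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)

  nearest_seed <- function(pix_idx, seed_idx) {
    # squared lattice distance from each pixel to each seed; ties -> first
    # (= lowest unit id, seeds are id-ordered)
    pr <- rows[pix_idx]; pc <- cols[pix_idx]
    sr <- rows[seed_idx]; sc <- cols[seed_idx]
    best <- rep(1L, length(pix_idx))
    bestd <- (pr - sr[1])^2 + (pc - sc[1])^2
    for (k in seq_along(seed_idx)[-1]) {
      d <- (pr - sr[k])^2 + (pc - sc[k])^2
      upd <- d < bestd
      best[upd] <- k
      bestd[upd] <- d[upd]
    }
    best
  }

  coarse_seeds <- sample.int(npix, config$n_coarse_units)
  coarse_assign <- nearest_seed(seq_len(npix), coarse_seeds)
  coarse_m <- matrix(coarse_assign, shape[1], shape[2])

  fine_m <- matrix(NA_integer_, shape[1], shape[2])
  fine_parent <- integer(0)
  next_fine <- 1L
  for (u in seq_len(config$n_coarse_units)) {
    pix <- which(coarse_assign == u)
    n_fine <- min(length(pix),
                  max(2L, stats::rpois(1, config$fine_per_coarse)))
    seeds <- if (length(pix) == 1L) pix else sample(pix, n_fine)
    sub <- nearest_seed(pix, seeds)
    sub <- match(sub, sort(unique(sub)))  # dense ids in case a seed owns no pixel
    fine_m[pix] <- next_fine - 1L + sub
    fine_parent <- c(fine_parent, rep(u, max(sub)))
    next_fine <- next_fine + max(sub)
  }

  apx <- pixel_area_km2(config$cell_size)
  mk_units <- function(m, parents) {
    ids <- sort(unique(as.vector(m)))
    np <- as.integer(table(factor(as.vector(m), levels = ids)))
    data.frame(unit_id = ids,
               parent_id = if (is.null(parents)) NA_integer_ else parents,
               n_pixels = np, area_km2 = np * apx, pop_count = NA_real_)
  }
  grid <- list(origin = config$origin, cell_size = config$cell_size,
               shape = shape)
  list(
    coarse = admin_layer(mk_units(coarse_m, NULL), coarse_m, grid, "coarse"),
    fine = admin_layer(mk_units(fine_m, fine_parent), fine_m, grid, "fine")
  )
}

# Largest-remainder apportionment of `total` (a non-negative integer) over
# weights >= 0; returns integers summing exactly to total.
apportion_integer <- function(weights, total) {
  if (total < 0) stop("total must be >= 0")
  if (all(weights <= 0)) weights <- rep(1, length(weights))
  q <- weights / sum(weights) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- q - base
    take <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  base
}

#' Simulate the true population surface
#'
#' Per-pixel intensity follows a log-linear model on the standardized
#' covariates, `lambda = exp(sum_k beta_k z_k + eps)` with
#' `eps ~ Normal(0, noise_sd)`; pixel populations are Poisson draws with
#' mean proportional to `lambda`, then rescaled and integerized by
#' largest-remainder apportionment so the grid total equals `pop_total`
#' exactly. Covariates named in `beta` but absent from the supplied set are
#' an error; covariates with zero variance enter as zero.
#'
#' @param config a [landscape_config()].
#' @param covariates named list of `raster_grid`s (see
#'   [generate_covariates()]).
#' @return a `raster_grid` of integer persons per pixel.
#' @export
simulate_population <- function(config, covariates) {
  validate_landscape_config(config)
  miss <- setdiff(names(config$beta), names(covariates))
  if (length(miss)) {
    stop("beta names covariates not supplied: ", paste(miss, collapse = ", "))
  }
  shape <- config$grid_shape
  npix <- prod(shape)
  set.seed(derive_seed(config$seed, "population"))

  eta <- rep(0, npix)
  for (nm in names(config$beta)) {
    z <- as.vector(covariates[[nm]]$values)
    s <- stats::sd(z)
    if (is.na(s) || s == 0) next
    eta <- eta + config$beta[[nm]] * (z - mean(z)) / s
  }
  eps <- if (config$noise_sd > 0) stats::rnorm(npix, 0, config$noise_sd) else 0
  lam <- exp(eta + eps)
  mean_pix <- lam / sum(lam) * config$pop_total
  draws <- stats::rpois(npix, mean_pix)
  pop <- apportion_integer(draws, round(config$pop_total))
  raster_grid(matrix(pop, shape[1], shape[2]), config$origin, config$cell_size)
}

#' Simulate geolocated point events
#'
#' Draws `N ~ Poisson(tweet_rate * pop_total)` events; each event's pixel
#' is sampled with probability proportional to
#' `true_population * (1 + road_bias * road_indicator)` and its coordinates
#' are uniform within the pixel. A `snap_fraction` share of events is then
#' relocated to the nearest of `snap_centroids` uniformly placed centroid
#' points, emulating coordinates quantized to named neighborhoods.
#'
#' @param config a [landscape_config()].
#' @param true_population `raster_grid` of persons per pixel.
#' @param covariates named covariate list; the `roa_cls` layer supplies the
#'   road indicator (all-zero if absent).
#' @return data.frame with columns `lon`, `lat` (possibly zero rows).
#' @export
simulate_events <- function(config, true_population, covariates) {
  validate_landscape_config(config)
  shape <- config$grid_shape
  set.seed(derive_seed(config$seed, "events"))
  n <- stats::rpois(1, config$tweet_rate * config$pop_total)
  if (n == 0) return(data.frame(lon = numeric(0), lat = numeric(0)))

  road <- if (!is.null(covariates$roa_cls)) {
    as.vector(covariates$roa_cls$values)
  } else rep(0, prod(shape))
  w <- as.vector(true_population$values) * (1 + config$road_bias * road)
  w[is.na(w)] <- 0
  if (sum(w) <= 0) w <- rep(1, length(w))
  pix <- sample.int(length(w), n, replace = TRUE, prob = w)

  cs <- config$cell_size
  row <- (pix - 1L) %% shape[1] + 1L
  col <- (pix - 1L) %/% shape[1] + 1L
  lon <- config$origin[1] + (col - 1 + stats::runif(n)) * cs
  lat <- config$origin[2] - (row - 1 + stats::runif(n)) * cs

  if (config$snap_fraction > 0 && config$snap_centroids > 0) {
    ext <- grid_extent(list(origin = config$origin, cell_size = cs,
                            shape = shape))
    clon <- stats::runif(config$snap_centroids, ext["xmin"], ext["xmax"])
    clat <- stats::runif(config$snap_centroids, ext["ymin"], ext["ymax"])
    snap <- stats::runif(n) < config$snap_fraction
    if (any(snap)) {
      d2 <- outer(lon[snap], clon, "-")^2 + outer(lat[snap], clat, "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      lon[snap] <- clon[nearest]
      lat[snap] <- clat[nearest]
    }
  }
  data.frame(lon = lon, lat = lat)
}

#' Generate a complete synthetic study region
#'
#' Runs the full generator: covariates, admin hierarchy, true population,
#' census counts at both levels, and point events. Deterministic given the
#' config (seed included); every stage draws from its own derived seed so
#' stages can be re-run independently.
#'
#' @param config a [landscape_config()].
#' @return list of class `synthetic_truth` with elements `config`,
#'   `covariates`, `true_population`, `admin_coarse`, `admin_fine`,
#'   `events`.
#' @export
generate_truth <- function(config) {
  covs <- generate_covariates(config)
  admin <- generate_admin_hierarchy(config)
  pop <- simulate_population(config, covs)
  census <- census_from_truth(pop, admin$coarse, admin$fine)
  events <- simulate_events(config, pop, covs)
  structure(list(config = config, covariates = covs, true_population = pop,
                 admin_coarse = census$coarse, admin_fine = census$fine,
                 events = events),
            class = "synthetic_truth")
}

#' Write a synthetic region to disk
#'
#' Serializes every component in plain-text formats: ASCII-grid rasters for
#' covariates and true population, GeoJSON for both admin levels, CSV
#' (`lon,lat`) for events, and the YAML config.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth$covariates)) {
    write_raster_asc(truth$covariates[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_raster_asc(truth$true_population, file.path(dir, "true_population.asc"))
  write_admin_geojson(truth$admin_coarse, file.path(dir, "admin_coarse.geojson"))
  write_admin_geojson(truth$admin_fine, file.path(dir, "admin_fine.geojson"))
  write_events_csv(truth$events, file.path(dir, "events.csv"))
  write_landscape_config(truth$config, file.path(dir, "config.yml"))
  invisible(dir)
}
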
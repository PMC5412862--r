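make_training_table <- function(n, seed, noise = 0) {
  # synthetic census units: density driven by one covariate, optional noise
  set.seed(seed)
  x <- runif(n)
  z <- rnorm(n)
  density <- exp(1 + 2 * x + noise * rnorm(n))
  tab <- data.frame(unit_id = seq_len(n), area_km2 = 1, pop_count = density,
                    density = density, drv = x, nse = z)
  attr(tab, "covariates") <- c("drv", "nse")
  class(tab) <- c("zonal_table", "data.frame")
  tab
}

test_that("zonal summaries equal the brute-force pixel loop", {
  cfg <- tiny_config(seed = 10)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  zt <- zonal_summarize(st, truth$admin_coarse)
  for (nm in names(st$layers)) {
    bf <- bf_zonal_mean(as.vector(st$layers[[nm]]$values),
                        as.vector(truth$admin_coarse$membership))
    expect_equal(setNames(zt[[nm]], zt$unit_id), bf, tolerance = 1e-12)
  }
  expect_equal(zt$density, zt$pop_count / zt$area_km2)
})

test_that("a uniform covariate summarizes to its value in every unit", {
  cfg <- tiny_config(seed = 11)
  adm <- generate_admin_hierarchy(cfg)
  adm$coarse$units$pop_count <- 100
  desc <- adm$coarse$grid
  st <- assemble_stack(list(
    flat = raster_grid(matrix(3.5, desc$shape[1], desc$shape[2]),
                       desc$origin, desc$cell_size)))
  zt <- zonal_summarize(st, adm$coarse)
  expect_true(all(zt$flat == 3.5))
})

test_that("the forest recovers a noise-free single-covariate signal", {
  tab <- make_training_table(200, seed = 1)
  fit <- fit_forest(tab, n_trees = 300, seed = 42)
  expect_gt(fit$oob_var_explained, 0.9)
  expect_lte(fit$oob_var_explained, 1)
  expect_setequal(names(fit$importance), c("drv", "nse"))
})

test_that("a pure-noise covariate ranks below the informative one", {
  wins <- 0
  for (s in 1:10) {
    tab <- make_training_table(120, seed = 100 + s, noise = 0.3)
    fit <- fit_forest(tab, n_trees = 200, seed = s)
    if (fit$importance["drv"] > fit$importance["nse"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("fitting is deterministic given table and seed", {
  tab <- make_training_table(60, seed = 2, noise = 0.2)
  f1 <- fit_forest(tab, n_trees = 100, seed = 7)
  f2 <- fit_forest(tab, n_trees = 100, seed = 7)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$oob_var_explained, f2$oob_var_explained)
})

test_that("degenerate training tables are rejected, constants tolerated", {
  tab <- make_training_table(5, seed = 3)
  expect_error(fit_forest(tab, seed = 1), "10 training units")
  tab2 <- make_training_table(50, seed = 4)
  tab2$density <- 7; tab2$pop_count <- 7
  expect_error(fit_forest(tab2, seed = 1), "zero variance")
  tab3 <- make_training_table(50, seed = 5)
  tab3$nse <- 1  # constant covariate: retained, zero importance
  fit <- fit_forest(tab3, n_trees = 100, seed = 1)
  expect_identical(unname(fit$importance["nse"]), 0)
})

test_that("log transform excludes zero-density units from training", {
  tab <- make_training_table(60, seed = 6)
  tab$density[1:5] <- 0
  fit <- fit_forest(tab, n_trees = 100, seed = 1)
  expect_equal(fit$n_train, 55)
})

test_that("raster prediction agrees with tabular prediction on matching rows", {
  cfg <- tiny_config(seed = 12, n_coarse_units = 14)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  zt <- zonal_summarize(st, truth$admin_coarse)
  fit <- fit_forest(zt, n_trees = 100, seed = 3)
  # build a constant stack pinned to one training row's covariate vector
  desc <- st$grid
  row1 <- zt[1, fit$covariates, drop = FALSE]
  const_layers <- lapply(as.list(row1), function(v)
    raster_grid(matrix(v, desc$shape[1], desc$shape[2]),
                desc$origin, desc$cell_size))
  roles <- setNames(rep("continuous", length(const_layers)), names(const_layers))
  w <- predict_weights(fit, assemble_stack(const_layers, descriptor = desc,
                                           roles = roles))
  expect_equal(unique(as.vector(w$values)),
               predict_density(fit, row1), tolerance = 1e-12)
})

test_that("missing covariate layers are reported by name", {
  cfg <- tiny_config(seed = 13, n_coarse_units = 14)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  fit <- fit_forest(zonal_summarize(st, truth$admin_coarse),
                    n_trees = 50, seed = 1)
  st$layers$lig <- NULL
  expect_error(predict_weights(fit, st), "lig")
})

test_that("nodata in a covariate propagates to the weight layer", {
  cfg <- tiny_config(seed = 14, n_coarse_units = 14)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  fit <- fit_forest(zonal_summarize(st, truth$admin_coarse),
                    n_trees = 50, seed = 1)
  st$layers$lig$values[5, 5] <- NA
  w <- predict_weights(fit, st)
  expect_true(is.na(w$values[5, 5]))
  expect_true(all(w$values[!is.na(w$values)] >= 0))
})

test_that("dasymetric redistribution conserves counts and honours weights", {
  cfg <- tiny_config(seed = 15)
  adm <- generate_admin_hierarchy(cfg)
  adm$coarse$units$pop_count <- seq(100, 600, by = 100)
  desc <- adm$coarse$grid

  unif <- raster_grid(matrix(1, desc$shape[1], desc$shape[2]),
                      desc$origin, desc$cell_size)
  m <- dasymetric_redistribute(unif, adm$coarse)
  # uniform weights: count / n_pixels per pixel within each unit
  for (i in seq_len(nrow(adm$coarse$units))) {
    uid <- adm$coarse$units$unit_id[i]
    px <- m$values[adm$coarse$membership == uid]
    expect_equal(px, rep(adm$coarse$units$pop_count[i] /
                           adm$coarse$units$n_pixels[i], length(px)))
  }

  # a single positive-weight pixel takes the whole unit count
  onew <- matrix(0, desc$shape[1], desc$shape[2])
  pick <- which(adm$coarse$membership == 1)[1]
  onew[pick] <- 1
  m2 <- dasymetric_redistribute(raster_grid(onew, desc$origin, desc$cell_size),
                                adm$coarse)
  expect_equal(m2$values[pick], adm$coarse$units$pop_count[1])
  expect_equal(attr(m2, "n_fallback_units"), 5)  # all-zero units fall back

  # scale equivariance: rescaling one unit's weights changes nothing
  set.seed(1)
  w <- matrix(runif(prod(desc$shape)), desc$shape[1], desc$shape[2])
  ma <- dasymetric_redistribute(raster_grid(w, desc$origin, desc$cell_size),
                                adm$coarse)
  w2 <- w; w2[adm$coarse$membership == 3] <- w2[adm$coarse$membership == 3] * 57
  mb <- dasymetric_redistribute(raster_grid(w2, desc$origin, desc$cell_size),
                                adm$coarse)
  expect_equal(ma$values, mb$values, tolerance = 1e-12)
})
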
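test_that("the generator is deterministic given the config", {
  cfg <- tiny_config(seed = 3)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$true_population$values, t2$true_population$values)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$admin_fine$membership, t2$admin_fine$membership)
  for (nm in names(t1$covariates)) {
    expect_identical(t1$covariates[[nm]]$values, t2$covariates[[nm]]$values)
  }
  # and byte-for-byte after serialization
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_truth(t1, d1); write_truth(t2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("covariate fields have the advertised structure", {
  covs <- generate_covariates(landscape_config(seed = 1, grid_shape = c(64, 64)))
  built <- covs$blt_cls$values
  expect_true(all(built %in% c(0, 1)))
  frac <- mean(built)
  expect_gt(frac, 0); expect_lt(frac, 1)
  # lights constructed from the same latent field: positive association
  expect_gt(cor(as.vector(covs$lig$values), as.vector(built)), 0.3)
  expect_true(any(covs$roa_cls$values == 1))
  expect_true(all(covs$ele$values >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(landscape_config(seed = 1, grid_shape = c(8, 64)), "16")
  expect_error(landscape_config(seed = 1, cell_size = 0), "cell_size")
  expect_error(landscape_config(seed = 1, n_coarse_units = 1), "n_coarse_units")
  expect_error(landscape_config(seed = 1, snap_fraction = 1.5), "snap_fraction")
  expect_error(landscape_config(seed = 1, grid_shape = c(16, 16),
                                n_coarse_units = 300), "pixel count")
  expect_error(landscape_config(), "seed")
})

test_that("admin hierarchy partitions the region and nests exactly", {
  cfg <- tiny_config(seed = 5)
  adm <- generate_admin_hierarchy(cfg)
  cm <- adm$coarse$membership; fm <- adm$fine$membership
  expect_false(anyNA(cm))
  expect_false(anyNA(fm))
  expect_setequal(unique(as.vector(cm)), adm$coarse$units$unit_id)
  expect_gte(nrow(adm$fine$units), nrow(adm$coarse$units))
  # every fine unit's pixels lie inside exactly one coarse unit, its parent
  for (i in seq_len(nrow(adm$fine$units))) {
    uid <- adm$fine$units$unit_id[i]
    parents <- unique(cm[fm == uid])
    expect_length(parents, 1)
    expect_equal(parents, adm$fine$units$parent_id[i])
  }
})

test_that("population is conserved and responds to the built covariate", {
  cfg <- tiny_config(seed = 2)
  covs <- generate_covariates(cfg)
  pop <- simulate_population(cfg, covs)
  expect_equal(sum(pop$values), cfg$pop_total)
  expect_true(all(pop$values >= 0))
  expect_true(all(pop$values == round(pop$values)))
  built <- covs$blt_cls$values == 1
  expect_gt(mean(pop$values[built]), mean(pop$values[!built]))
})

test_that("beta = 0 with no noise gives uniform expected intensity", {
  cfg <- tiny_config(seed = 4, noise_sd = 0,
                     beta = c(blt_cls = 0, lig = 0, roa_cls = 0, ele = 0))
  covs <- generate_covariates(cfg)
  pop <- simulate_population(cfg, covs)
  # Poisson(mean ~ 48.8) per pixel: the mean over 1024 pixels is tight
  expect_equal(mean(pop$values), cfg$pop_total / prod(cfg$grid_shape))
  expect_lt(sd(pop$values) / mean(pop$values), 0.25)
})

test_that("census counts sum and nest exactly across both levels", {
  cfg <- tiny_config(seed = 6)
  truth <- generate_truth(cfg)
  total <- sum(truth$true_population$values)
  expect_equal(sum(truth$admin_coarse$units$pop_count), total)
  expect_equal(sum(truth$admin_fine$units$pop_count), total)
  expect_equal(total, cfg$pop_total)
  by_parent <- tapply(truth$admin_fine$units$pop_count,
                      truth$admin_fine$units$parent_id, sum)
  coarse <- setNames(truth$admin_coarse$units$pop_count,
                     truth$admin_coarse$units$unit_id)
  expect_equal(as.numeric(by_parent[names(coarse)]), unname(coarse))
})

test_that("a single-unit layer's count is the grid total", {
  cfg <- tiny_config(seed = 7)
  covs <- generate_covariates(cfg)
  pop <- simulate_population(cfg, covs)
  shape <- cfg$grid_shape
  grid <- list(origin = cfg$origin, cell_size = cfg$cell_size, shape = shape)
  one <- admin_layer(
    data.frame(unit_id = 1L, parent_id = NA_integer_,
               n_pixels = prod(shape),
               area_km2 = prod(shape) * (cfg$cell_size * 111.32)^2,
               pop_count = NA_real_),
    matrix(1L, shape[1], shape[2]), grid, "all")
  filled <- census_from_truth(pop, one, one)
  expect_equal(filled$coarse$units$pop_count, sum(pop$values))
})

test_that("event simulation honours rate, bias switches and snapping", {
  cfg0 <- tiny_config(seed = 8, tweet_rate = 0)
  t0 <- generate_truth(cfg0)
  expect_equal(nrow(t0$events), 0)

  cfg <- tiny_config(seed = 8, tweet_rate = 0.05)
  truth <- generate_truth(cfg)
  expect_gt(nrow(truth$events), 0.5 * cfg$tweet_rate * cfg$pop_total)
  # unbiased events: per-pixel event counts track true population
  desc <- list(origin = cfg$origin, cell_size = cfg$cell_size,
               shape = cfg$grid_shape)
  loc <- locate_cells(desc, truth$events$lon, truth$events$lat)
  expect_true(all(loc$inside))
  counts <- matrix(0, cfg$grid_shape[1], cfg$grid_shape[2])
  tab <- table(loc$row + (loc$col - 1L) * cfg$grid_shape[1])
  counts[as.integer(names(tab))] <- as.integer(tab)
  expect_gt(cor(as.vector(counts), as.vector(truth$true_population$values),
                method = "spearman"), 0.3)

  snapped <- tiny_config(seed = 9, tweet_rate = 0.05, snap_fraction = 1,
                         snap_centroids = 5)
  ts <- generate_truth(snapped)
  expect_lte(length(unique(paste(ts$events$lon, ts$events$lat))), 5)
})

test_that("config round-trips through the key-value file and demands a seed", {
  cfg <- tiny_config(seed = 12, road_bias = 2, snap_fraction = 0.3)
  path <- withr::local_tempfile(fileext = ".yml")
  write_landscape_config(cfg, path)
  back <- read_landscape_config(path)
  expect_equal(unclass(back), unclass(cfg))
  lines <- readLines(path)
  writeLines(lines[!grepl("^seed", lines)], path)
  expect_error(read_landscape_config(path), "seed")
})
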
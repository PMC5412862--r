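test_that("aggregating the truth grid reproduces the fine census exactly", {
  cfg <- tiny_config(seed = 20)
  truth <- generate_truth(cfg)
  agg <- aggregate_to_units(truth$true_population, truth$admin_fine)
  obs <- setNames(truth$admin_fine$units$pop_count,
                  truth$admin_fine$units$unit_id)
  expect_equal(setNames(agg$pred_count, agg$unit_id), obs)
  expect_equal(sum(agg$pred_count), cfg$pop_total)

  # brute-force per-pixel loop agreement
  m <- as.vector(truth$admin_fine$membership)
  v <- as.vector(truth$true_population$values)
  bf <- tapply(v[!is.na(m)], m[!is.na(m)], sum)
  expect_equal(setNames(agg$pred_count, agg$unit_id),
               setNames(as.numeric(bf), names(bf)))
})

test_that("accuracy statistics match the hand-computed example", {
  rep_ <- accuracy(setNames(c(110, 190), c("1", "2")),
                   setNames(c(100, 200), c("1", "2")))
  expect_equal(rep_$rmse, 10)
  expect_equal(rep_$mae, 10)
  expect_equal(rep_$pct_rmse, 100 * 10 / 150)
  perfect <- accuracy(setNames(c(5, 7), c("1", "2")),
                      setNames(c(5, 7), c("1", "2")))
  expect_equal(c(perfect$rmse, perfect$mae, perfect$pct_rmse), c(0, 0, 0))
})

test_that("accuracy equals brute force and rmse >= mae on random instances", {
  set.seed(30)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    obs <- setNames(runif(n, 10, 1000), seq_len(n))
    pred <- obs + rnorm(n, 0, 50)
    rep_ <- accuracy(pred, obs)
    bf <- bf_accuracy(pred, obs)
    expect_equal(rep_$rmse, bf$rmse)
    expect_equal(rep_$mae, bf$mae)
    expect_equal(rep_$pct_rmse, bf$pct_rmse)
    expect_gte(rep_$rmse, rep_$mae)
  }
})

test_that("unit id mismatches are reported with the offending ids", {
  expect_error(
    accuracy(setNames(1:3, c("1", "2", "99")), setNames(1:3, c("1", "2", "3"))),
    "99")
})

test_that("comparison differences are algebraically consistent", {
  a <- accuracy_report("without", rmse = 2284.14, mae = 1123.44, pct_rmse = 74.58)
  b <- accuracy_report("with", rmse = 2213.99, mae = 1120.16, pct_rmse = 72.29)
  comp <- compare_accuracy(a, b)
  expect_equal(unname(comp$diff["rmse"]), a$rmse - b$rmse)
  tab <- comparison_table(comp)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rmse[3], tab$rmse[1] - tab$rmse[2])
  same <- compare_accuracy(a, a)
  expect_equal(unname(same$diff), c(0, 0, 0))
})

test_that("average spatial resolution follows its defining square root", {
  expect_equal(asr(100, 1), 10)
  expect_equal(asr(450, 2), sqrt(225))
  expect_error(asr(0, 10), "> 0")
  expect_error(asr(10, 0), "> 0")
})

test_that("difference maps are antisymmetric and conserve totals", {
  cfg <- tiny_config(seed = 21, n_coarse_units = 14)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  fit <- fit_forest(zonal_summarize(st, truth$admin_coarse),
                    n_trees = 80, seed = 1)
  w <- predict_weights(fit, st)
  map_a <- dasymetric_redistribute(w, truth$admin_coarse)
  map_b <- dasymetric_redistribute(truth$true_population, truth$admin_coarse)

  d <- difference_map(map_a, map_b)
  expect_equal(d$values, -difference_map(map_b, map_a)$values)
  zero <- difference_map(map_a, map_a)
  expect_true(all(zero$values[!is.na(zero$values)] == 0))
  # both maps conserve the same census, so the difference sums to ~0
  expect_lt(abs(sum(d$values, na.rm = TRUE)), 1e-6 * cfg$pop_total)
})

test_that("unit error maps agree with accuracy residuals unit by unit", {
  cfg <- tiny_config(seed = 22, n_coarse_units = 14)
  truth <- generate_truth(cfg)
  st <- build_model_stack(truth$covariates)
  fit <- fit_forest(zonal_summarize(st, truth$admin_coarse),
                    n_trees = 80, seed = 2)
  map <- dasymetric_redistribute(predict_weights(fit, st), truth$admin_coarse)
  pred <- aggregate_to_units(map, truth$admin_fine)
  obs <- data.frame(unit_id = truth$admin_fine$units$unit_id,
                    pop_count = truth$admin_fine$units$pop_count)
  rep_ <- accuracy(pred, obs)
  uem <- unit_error_map(pred, obs, truth$admin_fine)
  expect_equal(setNames(uem$errors$error, uem$errors$unit_id),
               rep_$residuals[as.character(uem$errors$unit_id)])
  expect_equal(sum(uem$errors$error),
               sum(pred$pred_count) - sum(obs$pop_count))
  # every pixel of a unit carries that unit's signed error
  uid <- uem$errors$unit_id[1]
  px <- uem$raster$values[truth$admin_fine$membership == uid]
  expect_true(all(px == uem$errors$error[1]))
})

test_that("comparison CSV has the three-row published-table shape", {
  a <- accuracy_report("Admin 3 without events", rmse = 100, mae = 60, pct_rmse = 40)
  b <- accuracy_report("Admin 3 with events", rmse = 90, mae = 55, pct_rmse = 36)
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(compare_accuracy(a, b), path)
  got <- read.csv(path)
  expect_equal(nrow(got), 3)
  expect_equal(names(got), c("model", "rmse", "pct_rmse", "mae"))
  expect_equal(got$rmse[3], 10)
})
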
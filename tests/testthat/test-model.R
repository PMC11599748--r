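test_that("tuning runs the requested grid deterministically with a stable RMSE", {
  scene <- make_scene(seed = 21, n_locations = 60, noise_sd = 0.003)
  folds <- random_folds(scene$mat, k = 3, seed = 1)
  tuned <- tune_ocd_model(scene$mat, folds, mtry = c(2, 3),
                          min_node = c(5, 10), n_trees = 50, seed = 2)
  expect_equal(nrow(tuned$results), 4)
  expect_true(all(is.finite(tuned$results$rmse)))
  expect_s3_class(tuned$selected, "model_spec")
  # random forests are insensitive to these knobs on smooth data
  expect_lt(tuned$rmse_spread, 0.1)
  tuned2 <- tune_ocd_model(scene$mat, folds, mtry = c(2, 3),
                           min_node = c(5, 10), n_trees = 50, seed = 2)
  expect_identical(tuned$results, tuned2$results)
})

test_that("fitting handles degenerate responses and is seed-reproducible", {
  scene <- make_scene(seed = 22, n_locations = 50)
  const <- scene$mat
  const$ocd_gcm3 <- 0.042
  const <- make_training(const, attr(scene$mat, "covariates"),
                         attr(scene$mat, "categorical"))
  m <- fit_ocd_model(const, model_spec(n_trees = 50))
  expect_equal(predict_ocd(m, const, depth = 15),
               rep(0.042, nrow(const)), tolerance = 1e-12)
  # all-zero response: predictions clipped/exact at zero
  zero <- const
  zero$ocd_gcm3 <- 0
  zero <- make_training(zero, attr(scene$mat, "covariates"),
                        attr(scene$mat, "categorical"))
  mz <- fit_ocd_model(zero, model_spec(n_trees = 50))
  expect_true(all(predict_ocd(mz, zero, depth = 15) == 0))
  # same seed, same forest
  m1 <- fit_ocd_model(scene$mat, model_spec(seed = 7, n_trees = 100))
  m2 <- fit_ocd_model(scene$mat, model_spec(seed = 7, n_trees = 100))
  expect_equal(predict_ocd(m1, scene$mat, depth = scene$mat$depth_cm),
               predict_ocd(m2, scene$mat, depth = scene$mat$depth_cm))
  # non-finite response rejected
  bad <- scene$mat
  bad$ocd_gcm3[1] <- NaN
  bad <- make_training(bad, attr(scene$mat, "covariates"),
                       attr(scene$mat, "categorical"))
  expect_error(fit_ocd_model(bad), "non-finite")
})

test_that("impurity importance identifies the driving predictor", {
  set.seed(9)
  n <- 400
  df <- data.frame(location_id = sprintf("l%d", seq_len(n)), depth_cm = 15,
                   strong = rnorm(n), weak = rnorm(n))
  df$ocd_gcm3 <- 0.05 + 0.02 * df$strong + rnorm(n, sd = 5e-4)
  mat <- make_training(df, c("strong", "weak"))
  m <- fit_ocd_model(mat, model_spec(mtry = 1, n_trees = 100))
  expect_equal(names(which.max(m$importance_norm)), "strong")
  expect_equal(sum(m$importance_norm), 1)
  expect_true(all(m$importance >= 0))
})

test_that("a pure-noise predictor ranks below truth-linked predictors across seeds", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 250
    df <- data.frame(location_id = sprintf("l%d", seq_len(n)), depth_cm = 15,
                     a = rnorm(n), b = rnorm(n), junk = rnorm(n))
    df$ocd_gcm3 <- 0.05 + 0.01 * df$a - 0.008 * df$b + rnorm(n, sd = 0.002)
    mat <- make_training(df, c("a", "b", "junk"))
    m <- fit_ocd_model(mat, model_spec(mtry = 2, n_trees = 100, seed = s))
    imp <- m$importance_norm
    if (imp["junk"] < imp["a"] && imp["junk"] < imp["b"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("prediction clips at zero, is depth-aware and near-interpolates dense noiseless data", {
  scene <- make_scene(seed = 23, n_locations = 250, cluster_fraction = 0.5,
                      noise_sd = 0, deep_retention = 1)
  m <- fit_ocd_model(scene$mat, model_spec(min_node = 1, n_trees = 300))
  # at training rows a deep forest is a near-interpolator
  pred <- predict_ocd(m, scene$mat, depth = scene$mat$depth_cm)
  expect_lt(mean(abs(pred - scene$mat$ocd_gcm3)),
            0.1 * sd(scene$mat$ocd_gcm3))
  expect_true(all(pred >= 0))
  # depth-monotone truth: predicted ordering at 0 vs 100 cm matches the sign
  scene2 <- make_scene(seed = 24, n_locations = 250, cluster_fraction = 0.5,
                       noise_sd = 0, deep_retention = 1)
  m2 <- fit_ocd_model(scene2$mat, model_spec())
  px <- pixel_table(scene2$grid)
  p0 <- predict_ocd(m2, px, depth = 0)
  p100 <- predict_ocd(m2, px, depth = 100)
  expect_gt(mean(p0 > p100), 0.9)  # truth has a negative depth effect
  # missing predictor named in the failure
  expect_error(predict_ocd(m2, px[, setdiff(names(px), "ndvi")], depth = 0),
               "ndvi")
})

test_that("categorical covariates are one-hot expanded consistently", {
  grid <- make_grid(seed = 25, covs = c("elev", "ctype"),
                    categorical = c(ctype = 3L))
  truth <- ocd_params(0.03, c(elev = -0.008, ctype = 0.01), noise_sd = 0)
  cores <- sample_cores(grid, truth,
                        sampling_design(120, 3, cluster_fraction = 0.5,
                                        seed = 5))
  mat <- suppressMessages(extract_covariates(cores, grid))
  m <- fit_ocd_model(mat, model_spec(n_trees = 100))
  expanded <- m$encoding$expanded
  expect_true(all(c("ctype_1", "ctype_2", "ctype_3") %in% expanded))
  expect_false("ctype" %in% expanded)
  expect_equal(length(m$importance_norm), length(expanded))
  p <- predict_ocd(m, pixel_table(grid), depth = 15)
  expect_true(all(is.finite(p)))
})
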
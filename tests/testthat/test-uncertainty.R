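test_that("the predictor space is standardized, scale-invariant and properly weighted", {
  scene <- make_scene(seed = 31, n_locations = 80)
  folds <- random_folds(scene$mat, k = 5, seed = 1)
  m <- fit_ocd_model(scene$mat, model_spec(n_trees = 100))
  space <- build_space(m, scene$mat, folds)
  # transformed training data has column means 0 and sds 1
  x <- marshstock:::encode_predictors(scene$mat, m$encoding)
  z <- sweep(sweep(x, 2, space$center), 2, space$scale, "/")
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-10)
  expect_equal(unname(apply(z[, !space$zero_sd, drop = FALSE], 2, sd)),
               rep(1, sum(!space$zero_sd)), tolerance = 1e-10)
  expect_equal(sum(space$weights), 1)
  # doubling the raw units of one predictor leaves DI unchanged
  set.seed(2)
  ref <- matrix(rnorm(60), 20, 3)
  q <- matrix(rnorm(15), 5, 3)
  w <- c(0.5, 0.3, 0.2)
  sp1 <- predictor_space(ref, colMeans(ref), apply(ref, 2, sd), w)
  ref2 <- ref; ref2[, 1] <- ref2[, 1] * 2
  q2 <- q; q2[, 1] <- q2[, 1] * 2
  sp2 <- predictor_space(ref2, colMeans(ref2), apply(ref2, 2, sd), w)
  expect_equal(di(q, sp1), di(q2, sp2), tolerance = 1e-12)
  # a zero-variance dimension is flagged and down-weighted to zero
  ref3 <- cbind(ref, 5)
  sp3 <- predictor_space(ref3, colMeans(ref3), apply(ref3, 2, sd),
                         c(w, 0.5))
  expect_true(sp3$zero_sd[4])
  expect_equal(sp3$weights[4], 0)
  expect_equal(sum(sp3$weights), 1)
})

test_that("DI matches hand computation and a brute-force oracle", {
  # 1-D reference {0, 1, 2}, identity transform, unit weight:
  # mean pairwise distance (1 + 2 + 1)/3 = 4/3; query at 4 -> 2 / (4/3) = 1.5
  sp <- predictor_space(matrix(c(0, 1, 2), 3, 1), center = 0, scale = 1,
                        weights = 1)
  expect_equal(di(matrix(4, 1, 1), sp), 1.5)
  expect_equal(di(matrix(1, 1, 1), sp), 0)  # identical reference point
  # brute-force oracle on a 200 x 200 random instance
  set.seed(4)
  ref <- matrix(rnorm(200 * 4), 200, 4)
  q <- matrix(rnorm(200 * 4), 200, 4)
  w <- runif(4); w <- w / sum(w)
  ctr <- colMeans(ref); scl <- apply(ref, 2, sd)
  sp2 <- predictor_space(ref, ctr, scl, w)
  expect_equal(di(q, sp2), brute_di(q, ref, ctr, scl, w), tolerance = 1e-10)
})

test_that("training DI excludes same-fold neighbours and errors when nothing remains", {
  set.seed(5)
  ref <- matrix(rnorm(40), 20, 2)
  sp <- predictor_space(ref, colMeans(ref), apply(ref, 2, sd), c(0.5, 0.5),
                        ref_folds = rep(1:2, each = 10))
  d_all <- di(ref, sp)
  d_excl <- di(ref, sp, exclude_fold = rep(1:2, each = 10))
  expect_true(all(d_all == 0))       # every point matches itself
  expect_true(all(d_excl > 0))       # own fold excluded: nearest is elsewhere
  sp_one <- predictor_space(ref, colMeans(ref), apply(ref, 2, sd),
                            c(0.5, 0.5), ref_folds = rep(1L, 20))
  expect_error(di(ref[1:2, ], sp_one, exclude_fold = c(1, 1)),
               "all reference points excluded")
})

test_that("AOA threshold follows the outlier rule under the type-7 quantile convention", {
  expect_equal(aoa_threshold(c(1, 2, 3, 4)), 5.5)
  expect_equal(aoa_threshold(rep(3, 10)), 3)
  set.seed(6)
  v <- rexp(101)
  expect_equal(aoa_threshold(v),
               manual_q7(v, 0.75) + 1.5 * (manual_q7(v, 0.75) - manual_q7(v, 0.25)))
  # threshold at or above the max => every training point inside
  v2 <- runif(50)
  thr <- aoa_threshold(v2)
  if (thr >= max(v2)) expect_true(all(v2 <= thr))
  expect_error(aoa_threshold(c(1, 2, 3)), ">= 4")
})

test_that("layer AOA requires being inside at both bounding depths", {
  di_maps <- list(`0` = matrix(c(0.5, 0.5, 2.0, 2.0), 2, 2),
                  `30` = matrix(c(0.5, 2.0, 0.5, 2.0), 2, 2))
  m <- aoa_mask(di_maps, threshold = 1, layer = c(0, 30))
  expect_equal(as.vector(m), c(TRUE, FALSE, FALSE, FALSE))
  # DI exactly at the threshold counts as inside
  di_eq <- list(`0` = matrix(1, 1, 1), `30` = matrix(1, 1, 1))
  expect_true(aoa_mask(di_eq, threshold = 1, layer = c(0, 30))[1, 1])
  expect_error(aoa_mask(di_maps, 1, layer = c(0, 100)), "missing")
})

test_that("error calibration is flat for homoscedastic residuals and tracks DI-linked noise", {
  set.seed(42)
  n <- 2000
  di_vals <- runif(n, 0, 2)
  cvh <- structure(list(samples = data.frame(residual = rnorm(n, sd = 0.05))),
                   class = "cv_result")
  em <- calibrate_error(cvh, di_vals)
  g <- seq(0, 2.5, length.out = 200)
  p <- predict(em, g)
  expect_lt(max(abs(p - em$overall_rmse) / em$overall_rmse), 0.15)
  # heteroscedastic: sd increasing in DI
  truesd <- 0.02 + 0.05 * di_vals
  cvi <- structure(list(samples = data.frame(residual = rnorm(n, sd = truesd))),
                   class = "cv_result")
  em2 <- calibrate_error(cvi, di_vals)
  p2 <- predict(em2, g)
  expect_true(all(diff(p2) >= -1e-12))           # monotone non-decreasing
  expect_gt(p2[length(p2)], p2[1])               # and genuinely increasing
  true_at_g <- 0.02 + 0.05 * pmin(g, max(em2$di))
  expect_gt(cor(p2, true_at_g, method = "spearman"), 0.9)
  # flat extrapolation beyond the fitted DI range
  expect_equal(predict(em2, 10), predict(em2, max(em2$di)))
  expect_equal(predict(em2, -1), predict(em2, min(em2$di)))
  # fewer samples than one window
  tiny <- structure(list(samples = data.frame(residual = rnorm(5))),
                    class = "cv_result")
  expect_error(calibrate_error(tiny, runif(5)), "window")
})

test_that("expected error propagates through the stock trapezoid", {
  grid <- make_grid(seed = 33, n = 8, mask_fraction = 1)
  const_em <- structure(list(di = c(0, 1), rmse = c(0.01, 0.01), window = 20,
                             overall_rmse = 0.01, constraint = "isotonic"),
                        class = "error_model")
  dis <- list(`0` = matrix(0.2, 8, 8), `30` = matrix(0.2, 8, 8),
              `100` = matrix(0.2, 8, 8))
  sp <- NULL  # DI surfaces precomputed; space not consulted
  e30 <- expected_error_surface(grid, sp, const_em, c(0, 30),
                                di_at_depths = dis)
  expect_true(all(e30 == 30 * 100 * 0.01))
  e70 <- expected_error_surface(grid, sp, const_em, c(30, 100),
                                di_at_depths = dis)
  # equal OCD-level error: deeper layer error scales with thickness
  expect_equal(unique(as.vector(e70 / e30)), 70 / 30)
})
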
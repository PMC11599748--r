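test_that("prediction points are drawn from the mask, deterministically", {
  grid <- make_grid(seed = 4)
  pts <- sample_prediction_points(grid, 100, seed = 2)
  expect_identical(pts, sample_prediction_points(grid, 100, seed = 2))
  cell <- marshstock:::grid_cell_index(grid, pts$lon, pts$lat)
  expect_true(all(grid$mask[cbind(cell$row, cell$col)]))
  n_mask <- sum(grid$mask)
  expect_warning(all_pts <- sample_prediction_points(grid, n_mask + 10, seed = 1),
                 "returning all")
  expect_equal(nrow(all_pts), n_mask)
})

test_that("nearest-neighbour distances match closed form and a brute-force oracle", {
  # two points one degree apart on the equator: 2 R asin(sin(0.5 deg))
  d <- nnd_ecdf(data.frame(lon = 0, lat = 0), data.frame(lon = 1, lat = 0))
  expect_equal(d, 2 * 6371 * asin(sin(0.5 * pi / 180)), tolerance = 0.5 / 111)
  # subset without self-exclusion: all zeros
  set.seed(7)
  pts <- data.frame(lon = runif(100, -10, 10), lat = runif(100, -30, 30))
  expect_true(all(nnd_ecdf(pts[1:10, ], pts) == 0))
  # brute-force O(n^2) oracle
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(pts))[-i], function(j) {
      haversine_km(pts$lon[i], pts$lat[i], pts$lon[j], pts$lat[j])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(nnd_ecdf(pts, pts, exclude_self = TRUE), sort(oracle),
               tolerance = 1e-12)
})

test_that("Wasserstein-1 on ECDFs behaves as a shift metric", {
  set.seed(2)
  x <- rnorm(50)
  expect_equal(wasserstein1(x, x), 0)
  expect_equal(wasserstein1(x, x + 2), 2, tolerance = 1e-10)
  expect_gt(wasserstein1(x, x * 3), 0)
})

test_that("k-NNDM recovers well-separated clusters and matches the enumeration oracle", {
  # 9 locations in 3 tight clusters; prediction points far from all of them
  set.seed(5)
  centres <- data.frame(lon = c(0, 5, 0), lat = c(0, 0, 5))
  loc <- data.frame(
    location_id = sprintf("l%d", 1:9),
    lon = rep(centres$lon, each = 3) + rnorm(9, sd = 0.01),
    lat = rep(centres$lat, each = 3) + rnorm(9, sd = 0.01)
  )
  truth_cluster <- rep(1:3, each = 3)
  preds <- data.frame(lon = runif(40, 19, 21), lat = runif(40, 19, 21))
  fa <- knndm_folds(loc, preds, k = 3)
  # folds = the clusters (up to labels)
  expect_equal(length(unique(fa$folds$fold)), 3)
  for (cl in 1:3) {
    expect_equal(length(unique(fa$folds$fold[truth_cluster == cl])), 1)
  }
  expect_equal(length(unique(fa$folds$fold[c(1, 4, 7)])), 3)
  # enumeration oracle: all surjective assignments of 9 points to 3 folds
  dmat <- haversine_matrix(loc$lon, loc$lat)
  target <- nnd_ecdf(preds, loc)
  qualities <- apply(expand.grid(rep(list(1:3), 9)), 1, function(f) {
    if (length(unique(f)) < 3) return(Inf)
    wasserstein1(marshstock:::between_fold_nnd(dmat, f), target)
  })
  expect_equal(fa$quality, min(qualities), tolerance = 1e-9)
  # deterministic: same inputs, same folds
  expect_identical(fa$folds, knndm_folds(loc, preds, k = 3)$folds)
})

test_that("with prediction points interleaved in the training data, k-NNDM matches at least as well as random folds", {
  grid <- make_grid(seed = 9, n = 48)
  scene_cores <- sample_cores(grid, default_truth(),
                              sampling_design(120, 3, cluster_fraction = 0,
                                              seed = 3))
  loc <- scene_cores[!duplicated(scene_cores$location_id), ]
  preds <- sample_prediction_points(grid, 300, seed = 8)
  kq <- knndm_folds(loc, preds, k = 5)$quality
  rq <- random_folds(loc, k = 5, seed = 1, prediction_points = preds)$quality
  expect_lte(kq, rq + 1e-12)
})

test_that("random folds are balanced, seeded and location-coherent", {
  scene <- make_scene(seed = 6, n_locations = 83)
  fa <- random_folds(scene$mat, k = 5, seed = 4)
  sizes <- table(fa$folds$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(fa$folds, random_folds(scene$mat, k = 5, seed = 4)$folds)
  # depth samples of one location always share its fold
  f <- marshstock:::fold_vector(scene$mat, fa)
  per_loc <- tapply(f, scene$mat$location_id, function(v) length(unique(v)))
  expect_true(all(per_loc == 1))
  expect_error(random_folds(scene$mat[1:3, ], k = 5), "fewer distinct")
})

test_that("cross-validation recovers noiseless structure and collapses under permutation", {
  scene <- make_scene(seed = 12, n_locations = 200, cluster_fraction = 0.5,
                      noise_sd = 0, deep_retention = 1)
  folds <- random_folds(scene$mat, k = 5, seed = 2)
  cv <- cross_validate(scene$mat, folds, model_spec(n_trees = 200))
  expect_gt(cv$r2, 0.95)
  expect_equal(cv$rmse,
               sqrt(mean((cv$samples$observed - cv$samples$predicted)^2)))
  expect_false(any(is.na(cv$samples$predicted)))
  expect_equal(nrow(cv$samples), nrow(scene$mat))
  # held-out predictions come from the assigned folds (no location leakage)
  expect_equal(cv$samples$fold, marshstock:::fold_vector(scene$mat, folds))
  # permuted response: no skill
  perm <- scene$mat
  set.seed(1)
  perm$ocd_gcm3 <- sample(perm$ocd_gcm3)
  perm <- make_training(perm, attr(scene$mat, "covariates"),
                        attr(scene$mat, "categorical"))
  cv_perm <- cross_validate(perm, folds, model_spec(n_trees = 200))
  expect_lte(cv_perm$r2, 0.05)
})
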
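# Spatial cross-validation with nearest-neighbour distance matching (k-NNDM):
# folds are chosen so that between-fold geographic distances mimic the
# distances from prediction locations to training locations. With clustered
# training data, random CV only measures within-cluster skill; distance-
# matched folds measure the model's ability to predict away from the clusters.

#' Sample prediction points from the marsh extent
#'
#' Uniform without-replacement sample of masked pixel centres, standing in
#' for the prediction locations the fitted model will be applied to.
#'
#' @param grid A `covariate_grid`.
#' @param n Number of points (default 5000). If the mask has fewer pixels,
#'   all are returned with a warning.
#' @param seed Integer seed.
#' @return Data frame with `lon`, `lat`.
#' @export
sample_prediction_points <- function(grid, n = 5000, seed = 1L) {
  masked <- which(grid$mask, arr.ind = TRUE)
  if (nrow(masked) == 0) stop("empty marsh mask")
  with_seed(seed, {
    if (n >= nrow(masked)) {
      if (n > nrow(masked)) {
        warning(sprintf("mask has only %d pixels; returning all of them",
                        nrow(masked)))
      }
      pick <- masked
    } else {
      pick <- masked[sample.int(nrow(masked), n), , drop = FALSE]
    }
    data.frame(lon = grid$lon[pick[, 2]], lat = grid$lat[pick[, 1]])
  })
}

unique_locations <- function(cores) {
  loc <- cores[!duplicated(cores$location_id),
               c("location_id", "lon", "lat"), drop = FALSE]
  rownames(loc) <- NULL
  loc
}

# Between-fold NN distances: for each location, distance to the nearest
# location assigned to a different fold. `dmat` is the precomputed pairwise
# great-circle distance matrix.
between_fold_nnd <- function(dmat, folds) {
  d <- dmat
  d[outer(folds, folds, "==")] <- Inf
  apply(d, 1, min)
}

# Assign clusters to k folds, largest first, each to the currently smallest
# fold (balanced greedy merge). Deterministic given cluster labels.
merge_clusters_to_k <- function(clusters, k) {
  sizes <- sort(table(clusters), decreasing = TRUE)
  fold_of_cluster <- integer(length(sizes))
  names(fold_of_cluster) <- names(sizes)
  fold_sizes <- numeric(k)
  for (i in seq_along(sizes)) {
    j <- which.min(fold_sizes)
    fold_of_cluster[i] <- j
    fold_sizes[j] <- fold_sizes[j] + sizes[i]
  }
  unname(fold_of_cluster[as.character(clusters)])
}

#' k-NNDM fold construction
#'
#' Builds `k` folds over unique training locations so that the empirical
#' distribution of between-fold nearest-neighbour geographic distances
#' matches the distribution of prediction-to-training nearest-neighbour
#' distances as closely as possible (Wasserstein-1 between the two ECDFs).
#'
#' The search space is a ladder of complete-linkage hierarchical clusterings
#' of the locations: the dendrogram is cut into q = k, k+1, ..., n clusters,
#' each cut is merged down to k folds by balanced greedy assignment, and the
#' configuration minimizing the Wasserstein distance wins; ties go to the cut
#' with fewer clusters. The achieved distance is stored as `quality`.
#'
#' @param train_coords Core table or location table with `location_id`,
#'   `lon`, `lat` (depth samples of one location always share its fold).
#' @param prediction_points Data frame of prediction locations (`lon`,
#'   `lat`), e.g. from [sample_prediction_points()].
#' @param k Number of folds (default 5).
#' @param max_cuts Cap on the number of ladder cuts examined (evenly spaced
#'   between k and n); keeps the search O(max_cuts * n^2).
#' @return A `fold_assignment`: data frame `folds` (`location_id`, `fold`),
#'   `k`, `quality` (achieved Wasserstein-1 distance in km), and the target
#'   and achieved NN-distance samples.
#' @export
knndm_folds <- function(train_coords, prediction_points, k = 5,
                        max_cuts = 400) {
  loc <- unique_locations(train_coords)
  n <- nrow(loc)
  if (n < k) stop("fewer distinct locations than folds")
  dmat <- haversine_matrix(loc$lon, loc$lat)
  target <- nnd_ecdf(prediction_points, loc)

  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  qs <- unique(round(seq(k, n, length.out = min(max_cuts, n - k + 1))))
  best <- NULL
  for (q in qs) {
    cl <- stats::cutree(hc, k = q)
    folds <- if (q == k) cl else merge_clusters_to_k(cl, k)
    if (length(unique(folds)) < k) next
    achieved <- between_fold_nnd(dmat, folds)
    w <- wasserstein1(achieved, target)
    if (is.null(best) || w < best$quality - 1e-12) {
      best <- list(folds = folds, quality = w, q = q, achieved = achieved)
    }
  }
  if (is.null(best)) stop("no valid fold configuration found")
  structure(
    list(folds = data.frame(location_id = loc$location_id,
                            fold = as.integer(best$folds)),
         k = as.integer(k), quality = best$quality,
         n_clusters = best$q, method = "knndm",
         target_nnd = target, achieved_nnd = sort(best$achieved)),
    class = "fold_assignment"
  )
}

#' Random location-level folds
#'
#' Uniform permutation of unique locations into k near-equal folds (sizes
#' differ by at most one). The baseline that k-NNDM is compared against;
#' `quality` is the same Wasserstein-1 match score when prediction points are
#' supplied.
#'
#' @param train_coords Core/location table with `location_id`, `lon`, `lat`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param prediction_points Optional prediction locations used to score the
#'   match quality of the random folds.
#' @return A `fold_assignment`.
#' @export
random_folds <- function(train_coords, k = 5, seed = 1L,
                         prediction_points = NULL) {
  loc <- unique_locations(train_coords)
  n <- nrow(loc)
  if (n < k) stop("fewer distinct locations than folds")
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(k), n))
    quality <- NA_real_
    achieved <- NULL
    if (!is.null(prediction_points)) {
      dmat <- haversine_matrix(loc$lon, loc$lat)
      achieved <- between_fold_nnd(dmat, folds)
      quality <- wasserstein1(achieved, nnd_ecdf(prediction_points, loc))
    }
    structure(
      list(folds = data.frame(location_id = loc$location_id,
                              fold = as.integer(folds)),
           k = as.integer(k), quality = quality, method = "random",
           achieved_nnd = if (!is.null(achieved)) sort(achieved)),
      class = "fold_assignment"
    )
  })
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment (%s): %d locations in %d folds\n",
              x$method, nrow(x$folds), x$k))
  print(table(fold = x$folds$fold))
  if (!is.na(x$quality)) {
    cat(sprintf("  ECDF match quality (Wasserstein-1): %.3f km\n", x$quality))
  }
  invisible(x)
}

fold_vector <- function(matrix, assignment) {
  f <- assignment$folds$fold[match(matrix$location_id,
                                   assignment$folds$location_id)]
  if (any(is.na(f))) stop("fold assignment does not cover all locations")
  f
}

#' Cross-validate an OCD model over spatial folds
#'
#' For each fold, fits the model on the remaining folds' samples and predicts
#' the held-out samples, so that every training sample receives exactly one
#' held-out prediction from a model that never saw its location. Aggregate
#' skill is R^2 = 1 - SSE/SST and RMSE over all held-out pairs.
#'
#' @param matrix A `training_matrix`.
#' @param folds A `fold_assignment` covering all of the matrix's locations.
#' @param spec A [model_spec()].
#' @return A `cv_result`: per-sample predictions/residuals with fold ids, and
#'   aggregate `r2` and `rmse` (g C cm^-3).
#' @export
cross_validate <- function(matrix, folds, spec = model_spec()) {
  f <- fold_vector(matrix, folds)
  pred <- rep(NA_real_, nrow(matrix))
  for (j in sort(unique(f))) {
    train <- matrix[f != j, , drop = FALSE]
    if (nrow(train) == 0) stop("fold ", j, " leaves an empty training set")
    attributes(train)[c("covariates", "categorical")] <-
      attributes(matrix)[c("covariates", "categorical")]
    class(train) <- class(matrix)
    m <- fit_ocd_model(train, spec)
    hold <- matrix[f == j, , drop = FALSE]
    pred[f == j] <- predict_ocd(m, hold, depth = hold$depth_cm)
  }
  obs <- matrix$ocd_gcm3
  resid <- obs - pred
  sse <- sum(resid^2)
  sst <- sum((obs - mean(obs))^2)
  structure(
    list(samples = data.frame(location_id = matrix$location_id,
                              fold = f, observed = obs, predicted = pred,
                              residual = resid),
         r2 = 1 - sse / sst,
         rmse = sqrt(mean(resid^2)),
         k = folds$k),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d held-out samples in %d folds\n",
              nrow(x$samples), x$k))
  cat(sprintf("  R2 = %.3f, RMSE = %.4f g C cm^-3\n", x$r2, x$rmse))
  invisible(x)
}
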
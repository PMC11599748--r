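# Area-of-applicability machinery: a dissimilarity index (DI) measured in the
# scaled, importance-weighted predictor space of the fitted model, an outlier
# threshold on the cross-validated training DI defining the AOA, and a
# monotone DI -> expected-RMSE calibration fitted on cross-validation
# residuals.

#' Low-level predictor-space constructor
#'
#' A predictor space is the coordinate system DI distances are measured in:
#' per-dimension centring/scaling constants (from training data only),
#' non-negative weights summing to 1, a reference matrix of transformed
#' training points and the mean pairwise distance among them (the DI
#' denominator, computed once).
#'
#' @param reference Numeric matrix of raw reference (training) predictor rows.
#' @param center,scale Per-column transform constants.
#' @param weights Per-column weights (>= 0; normalized to sum 1).
#' @param ref_folds Optional fold id per reference row (enables same-fold
#'   exclusion for training DI).
#' @return A `predictor_space`.
#' @export
predictor_space <- function(reference, center, scale, weights,
                            ref_folds = NULL) {
  reference <- as.matrix(reference)
  stopifnot(length(center) == ncol(reference),
            length(scale) == ncol(reference),
            length(weights) == ncol(reference), all(weights >= 0))
  if (sum(weights) == 0) stop("all predictor weights are zero")
  weights <- weights / sum(weights)
  zero_sd <- scale == 0
  scale[zero_sd] <- 1
  weights[zero_sd] <- 0
  if (sum(weights) == 0) stop("all non-degenerate predictor weights are zero")
  weights <- weights / sum(weights)
  ref_t <- sweep(sweep(reference, 2, center), 2, scale, "/")
  ref_w <- sweep(ref_t, 2, weights, "*")
  denom <- mean(stats::dist(ref_w))
  structure(
    list(center = center, scale = scale, weights = weights,
         zero_sd = zero_sd, ref_weighted = ref_w, ref_folds = ref_folds,
         denominator = denom, dims = colnames(reference)),
    class = "predictor_space"
  )
}

#' Build the DI predictor space from a fitted model
#'
#' Uses the model's one-hot encoding so that DI lives in exactly the space
#' the forest was fit in: per-dimension mean/sd from the training matrix and
#' weights equal to the normalized impurity importance. Zero-variance
#' dimensions receive weight 0 and are flagged.
#'
#' @param model A `fitted_model`.
#' @param matrix The `training_matrix` the model was fitted on.
#' @param folds Optional `fold_assignment`; stored per reference row so
#'   training DI can exclude same-fold neighbours.
#' @return A `predictor_space` with the model's encoding attached.
#' @export
build_space <- function(model, matrix, folds = NULL) {
  x <- encode_predictors(matrix, model$encoding)
  ref_folds <- if (!is.null(folds)) fold_vector(matrix, folds)
  sp <- predictor_space(
    reference = x,
    center = colMeans(x),
    scale = apply(x, 2, stats::sd),
    weights = model$importance_norm[colnames(x)],
    ref_folds = ref_folds
  )
  sp$encoding <- model$encoding
  sp
}

transform_to_space <- function(space, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(space$center))
  z <- sweep(sweep(x, 2, space$center), 2, space$scale, "/")
  sweep(z, 2, space$weights, "*")
}

# Min squared Euclidean distance from each row of Q to rows of R, with an
# optional logical exclusion matrix (nrow(Q) x nrow(R)).
min_cross_dist <- function(q, r, exclude = NULL) {
  s <- outer(rowSums(q^2), rep(1, nrow(r))) +
    outer(rep(1, nrow(q)), rowSums(r^2))
  d2 <- s - 2 * tcrossprod(q, r)
  # zap cancellation residue so identical vectors yield exactly 0 (DI contract)
  d2[d2 <= s * 1e-14] <- 0
  d2 <- pmax(d2, 0)
  if (!is.null(exclude)) d2[exclude] <- Inf
  mins <- apply(d2, 1, min)
  if (any(!is.finite(mins))) {
    stop("all reference points excluded for at least one query")
  }
  sqrt(mins)
}

#' Dissimilarity index
#'
#' DI of each query row: minimum weighted-Euclidean distance to the reference
#' (training) points in the predictor space, divided by the mean pairwise
#' distance among all training points. For training-data DI, pass
#' `exclude_fold` (one fold id per query row) so that neighbours in the same
#' cross-validation fold are ignored, mirroring how CV residuals were
#' produced; prediction-location DI uses all training points.
#'
#' @param query_rows Data frame of predictor rows (needs `depth_cm` unless
#'   `depth` is given) or an already-encoded numeric matrix.
#' @param space A `predictor_space` from [build_space()] or
#'   [predictor_space()].
#' @param exclude_fold Optional fold id per query row.
#' @param depth Optional depth (cm) overriding/creating the depth column
#'   (data-frame queries only).
#' @return Numeric DI vector (unitless, >= 0; 0 iff an identical predictor
#'   vector exists in the usable reference set).
#' @export
di <- function(query_rows, space, exclude_fold = NULL, depth = NULL) {
  stopifnot(inherits(space, "predictor_space"))
  x <- if (is.matrix(query_rows)) query_rows else {
    if (is.null(space$encoding)) {
      as.matrix(query_rows)
    } else {
      encode_predictors(query_rows, space$encoding, depth = depth)
    }
  }
  q <- transform_to_space(space, x)
  exclude <- NULL
  if (!is.null(exclude_fold)) {
    if (is.null(space$ref_folds)) {
      stop("space carries no reference fold ids; rebuild with folds")
    }
    exclude <- outer(exclude_fold, space$ref_folds, "==")
  }
  min_cross_dist(q, space$ref_weighted, exclude) / space$denominator
}

#' Training-data DI
#'
#' DI of every training row against the training reference with same-fold
#' exclusion — the sample the AOA threshold and the error calibration are
#' built from.
#'
#' @param space A `predictor_space` built with folds.
#' @param matrix The `training_matrix`.
#' @return Numeric DI vector aligned with the matrix rows.
#' @export
training_di <- function(space, matrix) {
  if (is.null(space$ref_folds)) {
    stop("space carries no reference fold ids; rebuild with folds")
  }
  di(matrix, space, exclude_fold = space$ref_folds)
}

#' AOA threshold from training DI
#'
#' The outlier-removed maximum of the cross-validated training DI:
#' Q75 + 1.5 * (Q75 - Q25), with quantiles under the linear-interpolation
#' (type 7) convention. Prediction locations whose DI exceeds this are
#' outside the area of applicability.
#'
#' @param training_di_values Numeric DI sample (>= 4 values).
#' @return Scalar threshold.
#' @export
aoa_threshold <- function(training_di_values) {
  stopifnot(length(training_di_values) >= 4)
  q <- stats::quantile(training_di_values, c(0.25, 0.75), names = FALSE,
                       type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Per-layer AOA mask from DI at the layer's bounding depths
#'
#' A pixel is inside the layer's AOA only if it is inside at both the upper
#' and lower standard depth: the two indicator rasters (DI <= threshold, the
#' boundary counting as inside) are averaged and only an average of exactly 1
#' is inside; averages of 0 or 0.5 are outside.
#'
#' @param di_at_depths Named list/map depth -> DI matrix (must contain both
#'   layer depths, keyed by their numeric value as character).
#' @param threshold AOA threshold from [aoa_threshold()].
#' @param layer Length-2 numeric `(top, bottom)` in cm.
#' @return Logical matrix: TRUE inside, FALSE outside, NA where DI is NA.
#' @export
aoa_mask <- function(di_at_depths, threshold, layer) {
  stopifnot(length(layer) == 2)
  keys <- as.character(layer)
  if (!all(keys %in% names(di_at_depths))) {
    stop("DI missing for depth(s): ",
         paste(setdiff(keys, names(di_at_depths)), collapse = ", "))
  }
  inside_top <- di_at_depths[[keys[1]]] <= threshold
  inside_bot <- di_at_depths[[keys[2]]] <= threshold
  (inside_top + inside_bot) / 2 == 1
}

#' Calibrate expected error as a monotone function of DI
#'
#' Sorts the cross-validation samples by their training DI, computes RMSE in
#' sliding windows along the DI axis, and fits an isotonic (monotone
#' non-decreasing) regression to the (window-centre DI, window RMSE) pairs.
#' Prediction beyond the fitted DI range extrapolates flat.
#'
#' @param cv A `cv_result` (per-sample residuals).
#' @param training_di DI per CV sample, same order as `cv$samples`.
#' @param window_fraction Window width as a fraction of the sample (default
#'   0.1).
#' @param min_window Minimum window size (default 20).
#' @return An `error_model`; use [predict.error_model()] to evaluate it.
#' @export
calibrate_error <- function(cv, training_di, window_fraction = 0.1,
                            min_window = 20) {
  resid <- cv$samples$residual
  stopifnot(length(training_di) == length(resid))
  n <- length(resid)
  w <- max(min_window, ceiling(window_fraction * n))
  if (w > n) stop("fewer samples (", n, ") than one window (", w, ")")
  ord <- order(training_di)
  d_sorted <- training_di[ord]
  r_sorted <- resid[ord]
  starts <- seq_len(n - w + 1)
  centre <- vapply(starts, function(i) mean(d_sorted[i:(i + w - 1)]),
                   numeric(1))
  rmse <- vapply(starts, function(i) sqrt(mean(r_sorted[i:(i + w - 1)]^2)),
                 numeric(1))
  iso <- stats::isoreg(centre, rmse)
  structure(
    list(di = iso$x, rmse = iso$yf, window = w,
         overall_rmse = sqrt(mean(resid^2)), constraint = "isotonic"),
    class = "error_model"
  )
}

#' Expected RMSE at given DI values
#'
#' Linear interpolation between fitted knots; flat extrapolation outside the
#' fitted DI range.
#'
#' @param object An `error_model`.
#' @param newdata Numeric DI values.
#' @param ... Unused.
#' @return Expected RMSE (g C cm^-3) per DI value.
#' @export
predict.error_model <- function(object, newdata, ...) {
  out <- rep(NA_real_, length(newdata))
  ok <- !is.na(newdata)
  out[ok] <- stats::approx(object$di, object$rmse, xout = newdata[ok],
                           rule = 2, ties = mean)$y
  out
}

#' DI surface over the marsh grid at a fixed depth
#'
#' @param grid A `covariate_grid`.
#' @param space A `predictor_space` with encoding (from [build_space()]).
#' @param depth Depth in cm.
#' @return Matrix of DI, NA outside the mask.
#' @export
di_surface <- function(grid, space, depth) {
  px <- pixel_table(grid)
  vals <- di(px, space, depth = depth)
  out <- matrix(NA_real_, length(grid$lat), length(grid$lon))
  out[cbind(px$row, px$col)] <- vals
  out
}

#' Expected-error surface for a stock layer
#'
#' Maps pixel DI at the layer's upper and lower standard depths through the
#' calibrated error model, then combines the two OCD-level expected errors
#' with the same trapezoid used for stocks: (e_top + e_bottom) / 2 x
#' thickness (cm) x 100, giving an expected error in Mg C ha^-1.
#'
#' @param grid A `covariate_grid`.
#' @param space A `predictor_space`.
#' @param error_model An `error_model`.
#' @param layer Length-2 `(top, bottom)` in cm.
#' @param di_at_depths Optional precomputed named list depth -> DI matrix
#'   (avoids recomputing DI surfaces).
#' @return Matrix of expected error in Mg C ha^-1, NA outside the mask.
#' @export
expected_error_surface <- function(grid, space, error_model, layer,
                                   di_at_depths = NULL) {
  stopifnot(length(layer) == 2)
  get_di <- function(d) {
    key <- as.character(d)
    if (!is.null(di_at_depths) && key %in% names(di_at_depths)) {
      di_at_depths[[key]]
    } else {
      di_surface(grid, space, d)
    }
  }
  e_top <- matrix(predict(error_model, as.vector(get_di(layer[1]))),
                  length(grid$lat), length(grid$lon))
  e_bot <- matrix(predict(error_model, as.vector(get_di(layer[2]))),
                  length(grid$lat), length(grid$lon))
  thickness <- layer[2] - layer[1]
  (e_top + e_bot) / 2 * thickness * 100
}
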
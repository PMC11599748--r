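# Depth-augmented random forest for organic carbon density: depth (cm) enters
# as an ordinary predictor next to the landscape covariates, so one model
# serves every standard prediction depth. Categorical covariates are one-hot
# expanded before fitting, and the same expansion map is reused by the
# dissimilarity-index machinery so that model and uncertainty share one
# predictor space.

#' Random forest specification
#'
#' Defaults are the pinned production settings: mtry 3, minimum node size 5,
#' 300 trees, impurity (variance-reduction) importance.
#'
#' @param mtry Predictors tried at each split (capped at the number of
#'   expanded predictors at fit time).
#' @param min_node Minimum node size.
#' @param n_trees Number of trees.
#' @param importance_mode Importance mode; only "impurity" is supported.
#' @param seed Integer seed for tree growing.
#' @return A `model_spec`.
#' @export
model_spec <- function(mtry = 3L, min_node = 5L, n_trees = 300L,
                       importance_mode = "impurity", seed = 1L) {
  stopifnot(mtry >= 1, n_trees >= 1, min_node >= 1,
            importance_mode == "impurity")
  structure(
    list(mtry = as.integer(mtry), min_node = as.integer(min_node),
         n_trees = as.integer(n_trees), importance_mode = importance_mode,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

# Restore training_matrix attributes lost by data.frame subsetting.
subset_training <- function(matrix, idx) {
  out <- as.data.frame(matrix)[idx, , drop = FALSE]
  attr(out, "covariates") <- attr(matrix, "covariates")
  attr(out, "categorical") <- attr(matrix, "categorical")
  class(out) <- c("training_matrix", "data.frame")
  rownames(out) <- NULL
  out
}

# One-hot expansion map learned from training data: categorical predictors
# become one indicator column per observed class.
build_encoding <- function(data, covariates, categorical) {
  levels <- lapply(categorical, function(nm) sort(unique(data[[nm]])))
  names(levels) <- categorical
  continuous <- setdiff(covariates, categorical)
  expanded <- c("depth_cm", continuous,
                unlist(lapply(categorical, function(nm) {
                  paste0(nm, "_", levels[[nm]])
                })))
  list(covariates = covariates, continuous = continuous,
       categorical = categorical, levels = levels, expanded = expanded)
}

# Apply the one-hot map; `depth` overrides/creates the depth column.
encode_predictors <- function(data, encoding, depth = NULL) {
  n <- nrow(data)
  missing_cols <- setdiff(encoding$covariates, names(data))
  if (length(missing_cols)) {
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(depth)) {
    if (!"depth_cm" %in% names(data)) stop("missing predictor column: depth_cm")
    depth <- data$depth_cm
  }
  out <- matrix(0, n, length(encoding$expanded),
                dimnames = list(NULL, encoding$expanded))
  out[, "depth_cm"] <- rep_len(depth, n)
  for (nm in encoding$continuous) out[, nm] <- data[[nm]]
  for (nm in encoding$categorical) {
    for (lv in encoding$levels[[nm]]) {
      out[, paste0(nm, "_", lv)] <- as.numeric(data[[nm]] == lv)
    }
  }
  out
}

#' Fit the OCD random forest
#'
#' @param matrix A `training_matrix` (response `ocd_gcm3`, predictor
#'   `depth_cm` plus covariates).
#' @param spec A [model_spec()].
#' @return A `fitted_model`: the ranger ensemble, the one-hot encoding map,
#'   raw and normalized (sum 1) impurity importance, and a training summary.
#' @export
fit_ocd_model <- function(matrix, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(!is.finite(matrix$ocd_gcm3))) stop("non-finite response values")
  encoding <- build_encoding(matrix, attr(matrix, "covariates"),
                             attr(matrix, "categorical"))
  x <- encode_predictors(matrix, encoding)
  fit <- ranger::ranger(
    x = x, y = matrix$ocd_gcm3,
    num.trees = spec$n_trees,
    mtry = min(spec$mtry, ncol(x)),
    min.node.size = spec$min_node,
    importance = "impurity",
    seed = spec$seed,
    num.threads = 1
  )
  imp <- fit$variable.importance
  imp_norm <- if (sum(imp) > 0) imp / sum(imp) else
    rep(1 / length(imp), length(imp))
  structure(
    list(forest = fit, encoding = encoding, spec = spec,
         importance = imp, importance_norm = imp_norm,
         n_samples = nrow(matrix),
         oob_rmse = sqrt(fit$prediction.error)),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %d trees, mtry %d, min node %d, %d samples\n",
              x$spec$n_trees, x$spec$mtry, x$spec$min_node, x$n_samples))
  cat(sprintf("  OOB RMSE: %.4f g C cm^-3\n", x$oob_rmse))
  top <- sort(x$importance_norm, decreasing = TRUE)
  cat("  top importance:",
      paste(sprintf("%s (%.2f)", names(top)[seq_len(min(3, length(top)))],
                    top[seq_len(min(3, length(top)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict OCD for covariate rows at a depth
#'
#' Vectorized prediction; `depth` may be a scalar (one standard depth for all
#' rows) or a per-row vector. Predictions are clipped at 0 since a density
#' cannot be negative.
#'
#' @param model A `fitted_model`.
#' @param covariate_rows Data frame carrying all model covariates.
#' @param depth Depth(s) in cm.
#' @return Numeric vector of OCD, g C cm^-3.
#' @export
predict_ocd <- function(model, covariate_rows, depth) {
  stopifnot(inherits(model, "fitted_model"))
  x <- encode_predictors(covariate_rows, model$encoding, depth = depth)
  p <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  pmax(p, 0)
}

#' Hyperparameter tuning over the standard grid
#'
#' Cross-validated RMSE for every combination of mtry x min_node x n_trees,
#' using the supplied (typically k-NNDM) folds. Selection is the lowest RMSE;
#' ties are broken toward fewer trees, then larger minimum node size.
#'
#' @param matrix A `training_matrix`.
#' @param folds A `fold_assignment`.
#' @param mtry,min_node,n_trees Grid axes; defaults are the standard 5 x 5 x
#'   5 tuning grid.
#' @param seed Seed passed to every candidate fit.
#' @return List with `results` (the full tuning table, one RMSE per
#'   combination) and `selected` (a [model_spec()]).
#' @export
tune_ocd_model <- function(matrix, folds,
                           mtry = 1:5,
                           min_node = c(1, 2, 3, 5, 10),
                           n_trees = c(100, 200, 300, 400, 500),
                           seed = 1L) {
  grid <- expand.grid(mtry = mtry, min_node = min_node, n_trees = n_trees)
  if (nrow(grid) == 0) stop("empty tuning grid")
  grid$rmse <- NA_real_
  grid$r2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    spec <- model_spec(grid$mtry[i], grid$min_node[i], grid$n_trees[i],
                       seed = seed)
    cv <- cross_validate(matrix, folds, spec)
    grid$rmse[i] <- cv$rmse
    grid$r2[i] <- cv$r2
  }
  ord <- order(grid$rmse, grid$n_trees, -grid$min_node)
  best <- grid[ord[1], ]
  list(
    results = grid,
    selected = model_spec(best$mtry, best$min_node, best$n_trees, seed = seed),
    rmse_spread = (max(grid$rmse) - min(grid$rmse)) / mean(grid$rmse)
  )
}
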
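# Shared fixtures: small synthetic landscapes and independent oracles.

make_grid <- function(seed = 1, n = 32, covs = c("elev", "ndvi", "tide"),
                      smoothness = 0.1, res = 0.02, categorical = integer(),
                      mask_fraction = 0.4) {
  spec <- grid_spec(0, n * res, 40, 40 + n * res, res, seed = seed)
  generate_covariate_grid(spec, covs, smoothness, categorical = categorical,
                          mask_fraction = mask_fraction)
}

default_truth <- function(noise_sd = 0, depth_effect = -5e-5) {
  ocd_params(0.03, c(elev = -0.008, ndvi = 0.006, tide = 0.004),
             depth_effect = depth_effect, noise_sd = noise_sd)
}

# Wrap a plain data frame as a training matrix.
make_training <- function(df, covariates, categorical = character()) {
  attr(df, "covariates") <- covariates
  attr(df, "categorical") <- categorical
  class(df) <- c("training_matrix", "data.frame")
  df
}

# Grid + clustered cores + extracted training matrix in one call.
make_scene <- function(seed = 1, n = 32, n_locations = 150,
                       cluster_fraction = 0.85, cluster_sd = 0.04,
                       noise_sd = 0, deep_retention = 0.35, ...) {
  grid <- make_grid(seed = seed, n = n)
  truth <- default_truth(noise_sd = noise_sd)
  design <- sampling_design(n_locations, 3, cluster_fraction = cluster_fraction,
                            cluster_sd = cluster_sd,
                            deep_retention = deep_retention,
                            seed = seed + 1000, ...)
  cores <- sample_cores(grid, truth, design)
  mat <- suppressMessages(extract_covariates(cores, grid))
  list(grid = grid, truth = truth, cores = cores, mat = mat)
}

# Brute-force Moran's I with rook neighbours (symmetric binary weights).
moran_i <- function(m) {
  x <- m - mean(m)
  s_h <- sum(x[, -ncol(m)] * x[, -1])
  s_v <- sum(x[-nrow(m), ] * x[-1, ])
  w <- 2 * (nrow(m) * (ncol(m) - 1) + (nrow(m) - 1) * ncol(m))
  (length(m) / w) * (2 * (s_h + s_v)) / sum(x^2)
}

# Brute-force DI oracle: explicit loops, no shared code with di().
brute_di <- function(query, ref, center, scale, weights) {
  weights <- weights / sum(weights)
  tq <- sweep(sweep(query, 2, center), 2, scale, "/")
  tr <- sweep(sweep(ref, 2, center), 2, scale, "/")
  wd <- function(a, b) sqrt(sum((weights * (a - b))^2))
  denom_sum <- 0; n <- nrow(tr); npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom_sum <- denom_sum + wd(tr[i, ], tr[j, ]); npairs <- npairs + 1
  }
  denom <- denom_sum / npairs
  vapply(seq_len(nrow(tq)), function(i) {
    min(vapply(seq_len(n), function(j) wd(tq[i, ], tr[j, ]), numeric(1))) /
      denom
  }, numeric(1))
}

# Type-7 quantile computed by hand (sorted linear interpolation).
manual_q7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Bare layer_stock_map constructor for aggregation tests.
make_stock_map <- function(grid, stocks, errors = NULL, masked = FALSE) {
  layers <- list()
  for (key in names(stocks)) {
    bounds <- as.numeric(strsplit(key, "-")[[1]])
    err <- if (!is.null(errors)) errors[[key]]
    layers[[key]] <- list(top = bounds[1], bottom = bounds[2],
                          stock = stocks[[key]], expected_error = err,
                          aoa = NULL, stock_premask = stocks[[key]],
                          error_premask = err)
  }
  structure(list(grid = grid, layers = layers, ocd_surfaces = NULL,
                 masked = masked),
            class = "layer_stock_map")
}
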
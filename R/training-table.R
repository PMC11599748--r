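# Assembly and screening of the model's training matrix: latitude/mask
# filtering of core sites, OCD computation, nearest-pixel covariate
# extraction, collinearity screening, and covariate-coverage diagnostics.

#' Filter core sites by latitude band and optional mask
#'
#' Removes cores outside the latitude band (default 60° S–60° N, the band
#' covered by the covariate products) and, when a grid is supplied, cores
#' falling outside its marsh mask. Counts of removed rows are reported via
#' `message()` and attached as the `"n_removed"` attribute.
#'
#' @param cores Core table with at least `lon`, `lat`.
#' @param lat_min,lat_max Latitude band, decimal degrees.
#' @param mask Optional `covariate_grid`; cores off its marsh mask are
#'   dropped.
#' @return Filtered core table.
#' @export
filter_sites <- function(cores, lat_min = -60, lat_max = 60, mask = NULL) {
  stopifnot(nrow(cores) > 0)
  in_band <- cores$lat >= lat_min & cores$lat <= lat_max
  n_band <- sum(!in_band)
  out <- cores[in_band, , drop = FALSE]
  n_mask <- 0L
  if (!is.null(mask) && nrow(out) > 0) {
    cell <- grid_cell_index(mask, out$lon, out$lat)
    on_mask <- !is.na(cell$row) & !is.na(cell$col) &
      mask$mask[cbind(cell$row, cell$col)]
    on_mask[is.na(on_mask)] <- FALSE
    n_mask <- sum(!on_mask)
    out <- out[on_mask, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    stop("all cores removed by latitude/mask filtering")
  }
  if (n_band + n_mask > 0) {
    message(sprintf("filter_sites: removed %d rows outside latitude band, %d off mask",
                    n_band, n_mask))
  }
  attr(out, "n_removed") <- c(latitude = n_band, mask = n_mask)
  rownames(out) <- NULL
  out
}

#' Organic carbon density from bulk density and carbon fraction
#'
#' OCD (g C cm^-3) = dry bulk density (g cm^-3) x organic carbon fraction
#' (unitless, 0–1). A fraction above 1 almost always means percent was passed
#' and is rejected.
#'
#' @param bulk_density Dry bulk density, g cm^-3 (>= 0).
#' @param oc_fraction Organic carbon mass fraction in 0–1.
#' @return OCD in g C cm^-3.
#' @export
compute_ocd <- function(bulk_density, oc_fraction) {
  if (any(bulk_density < 0) || any(oc_fraction < 0)) {
    stop("bulk_density and oc_fraction must be non-negative")
  }
  if (any(oc_fraction > 1)) {
    stop("oc_fraction > 1: expected a 0-1 fraction, not a percent")
  }
  bulk_density * oc_fraction
}

#' Extract covariates at core locations
#'
#' Nearest-pixel (pixel-containing) lookup of every grid covariate at each
#' core's coordinates, producing the training matrix: one row per depth
#' sample with the response `ocd_gcm3`, the `depth_cm` predictor, and one
#' column per covariate. Cores on nodata (off-mask) pixels are dropped with a
#' logged count; cores outside the grid bounds are an error.
#'
#' @param cores Core table (`location_id`, `lon`, `lat`, `depth_cm`,
#'   `ocd_gcm3`, optional `region`).
#' @param grid A `covariate_grid`.
#' @return A data frame of class `training_matrix` with attribute
#'   `"covariates"` (predictor names) and `"categorical"`.
#' @export
extract_covariates <- function(cores, grid) {
  stopifnot(nrow(cores) > 0, inherits(grid, "covariate_grid"))
  cell <- grid_cell_index(grid, cores$lon, cores$lat)
  outside <- is.na(cell$row) | is.na(cell$col)
  if (any(outside)) {
    stop("core location(s) outside grid bounds: ",
         paste(unique(cores$location_id[outside]), collapse = ", "))
  }
  on_mask <- grid$mask[cbind(cell$row, cell$col)]
  n_drop <- sum(!on_mask)
  if (n_drop > 0) {
    message(sprintf("extract_covariates: dropped %d rows on nodata pixels",
                    n_drop))
  }
  keep <- which(on_mask)
  out <- cores[keep, , drop = FALSE]
  for (nm in names(grid$data)) {
    out[[nm]] <- grid$data[[nm]][cbind(cell$row[keep], cell$col[keep])]
  }
  complete <- stats::complete.cases(out[, names(grid$data), drop = FALSE])
  if (any(!complete)) {
    message(sprintf("extract_covariates: dropped %d rows with missing covariates",
                    sum(!complete)))
    out <- out[complete, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "covariates") <- names(grid$data)
  attr(out, "categorical") <- grid$categorical
  attr(out, "n_dropped") <- n_drop + sum(!complete)
  class(out) <- c("training_matrix", "data.frame")
  out
}

#' Pairwise collinearity screen
#'
#' Pearson correlations among continuous covariates, flagging pairs whose
#' |r| exceeds the threshold. Advisory only: flagged covariates are reported,
#' not removed (the global model retained all 13 of its covariates under the
#' same rule).
#'
#' @param matrix A `training_matrix`.
#' @param threshold Flagging threshold on |r| (default 0.7).
#' @return Data frame with `var1`, `var2`, `r`, `flag`; `r` is NA with
#'   `note = "constant column"` for degenerate pairs.
#' @export
collinearity_screen <- function(matrix, threshold = 0.7) {
  covs <- setdiff(attr(matrix, "covariates"), attr(matrix, "categorical"))
  if (length(covs) < 2) stop("need at least two continuous covariates")
  pairs <- utils::combn(covs, 2)
  res <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = NA_real_,
                    flag = FALSE, note = "")
  for (i in seq_len(ncol(pairs))) {
    x <- matrix[[pairs[1, i]]]; y <- matrix[[pairs[2, i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      res$note[i] <- "constant column"
    } else {
      res$r[i] <- stats::cor(x, y)
      res$flag[i] <- abs(res$r[i]) > threshold
    }
  }
  res
}

#' Covariate coverage of the training data
#'
#' Compares the training distribution of each covariate with its distribution
#' over the whole marsh extent, using `n_background` random marsh pixels:
#' matched quantiles and a two-sample Kolmogorov-Smirnov statistic per
#' covariate. Large KS values indicate covariate ranges the training data do
#' not represent.
#'
#' @param matrix A `training_matrix`.
#' @param grid The `covariate_grid` the matrix was extracted from.
#' @param n_background Number of random background pixels (default 10000;
#'   sampled with replacement when the mask is smaller).
#' @param seed Integer seed for the background draw.
#' @param probs Quantile probabilities reported for both distributions.
#' @return Data frame with one row per covariate x quantile, plus a `ks`
#'   column (repeated within covariate).
#' @export
coverage_report <- function(matrix, grid, n_background = 10000, seed = 1L,
                            probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(grid, "covariate_grid"))
  masked <- which(grid$mask, arr.ind = TRUE)
  if (nrow(masked) == 0) stop("empty marsh mask")
  covs <- attr(matrix, "covariates")
  with_seed(seed, {
    pick <- masked[sample.int(nrow(masked), n_background, replace = TRUE), ,
                   drop = FALSE]
    out <- lapply(covs, function(nm) {
      bg <- grid$data[[nm]][pick]
      tr <- matrix[[nm]]
      ks <- suppressWarnings(stats::ks.test(tr, bg)$statistic)
      data.frame(covariate = nm, prob = probs,
                 q_training = stats::quantile(tr, probs, names = FALSE),
                 q_background = stats::quantile(bg, probs, names = FALSE),
                 ks = as.numeric(ks))
    })
    do.call(rbind, out)
  })
}
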
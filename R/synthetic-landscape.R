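# Synthetic tidal-marsh landscapes: spatially autocorrelated covariates over a
# marsh mask, a known generative OCD(x, y, depth) truth, and clustered,
# depth-stratified soil-core sampling. Everything downstream of the generator
# treats its output exactly like field data.

#' Grid specification
#'
#' Defines a regular lon/lat grid with centre-registered pixels, row-major
#' from the north-west corner. Latitudes are restricted to 60° S–60° N,
#' matching the band where global tidal-marsh extent products are defined.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid bounds in decimal degrees.
#' @param resolution Pixel size in degrees.
#' @param seed Integer seed controlling all randomness of grids built from
#'   this spec.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, resolution,
                      seed = 1L) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, resolution > 0)
  if (lat_min < -60 || lat_max > 60) {
    stop("latitudes must lie within the 60° S to 60° N band")
  }
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         resolution = resolution, seed = as.integer(seed)),
    class = "grid_spec"
  )
}

#' Generative OCD parameters
#'
#' Parameters of the linear-additive ground-truth organic carbon density
#' field: OCD = intercept + sum(effects * covariate) + depth_effect * depth,
#' clipped at `floor`. Depth effects near zero give the near-flat density
#' profiles typical of tidal-marsh soils. `noise_sd` is only applied when
#' sampling cores; the truth field itself is noise-free.
#'
#' @param intercept Baseline OCD, g C cm^-3.
#' @param effects Named numeric vector of per-covariate coefficients (on the
#'   standardized covariate scale; categorical covariates enter via their
#'   integer class code).
#' @param depth_effect Coefficient per cm of depth.
#' @param noise_sd Standard deviation of additive measurement noise
#'   (g C cm^-3), >= 0.
#' @param floor Lower clip for generated OCD, >= 0.
#' @return An object of class `ocd_params`.
#' @export
ocd_params <- function(intercept, effects = numeric(), depth_effect = 0,
                       noise_sd = 0, floor = 0) {
  stopifnot(noise_sd >= 0, floor >= 0)
  if (length(effects) && is.null(names(effects))) {
    stop("'effects' must be a named vector of covariate coefficients")
  }
  structure(
    list(intercept = intercept, effects = effects,
         depth_effect = depth_effect, noise_sd = noise_sd, floor = floor),
    class = "ocd_params"
  )
}

#' Core sampling design
#'
#' Emulates the geography of real blue-carbon soil datasets: most locations
#' fall in a few dense national clusters (over 85% in three countries in the
#' global compilations) and deep layers are undersampled (roughly 35% of
#' samples below 30 cm).
#'
#' @param n_locations Number of unique core locations.
#' @param n_clusters Number of Gaussian sampling clusters.
#' @param cluster_fraction Proportion of locations drawn from clusters
#'   (remainder uniform over the marsh mask).
#' @param cluster_sd Cluster spread, degrees.
#' @param depth_grid Layer-centre sampling depths, cm (all > 0).
#' @param deep_retention Probability that a location retains its samples
#'   below 30 cm.
#' @param seed Integer seed.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(n_locations = 300L, n_clusters = 3L,
                            cluster_fraction = 0.85, cluster_sd = 0.05,
                            depth_grid = c(5, 15, 25, 45, 75, 95),
                            deep_retention = 0.35, seed = 1L) {
  stopifnot(cluster_fraction >= 0, cluster_fraction <= 1,
            deep_retention > 0, deep_retention <= 1,
            all(depth_grid > 0), n_locations >= n_clusters)
  structure(
    list(n_locations = as.integer(n_locations),
         n_clusters = as.integer(n_clusters),
         cluster_fraction = cluster_fraction, cluster_sd = cluster_sd,
         depth_grid = depth_grid, deep_retention = deep_retention,
         seed = as.integer(seed)),
    class = "sampling_design"
  )
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  w <- stats::dnorm(seq(-r, r), sd = max(sigma_px, .Machine$double.eps))
  if (sum(w) == 0) w[r + 1] <- 1
  w / sum(w)
}

# Separable Gaussian smoothing with circular wrap (keeps fields stationary;
# edge effects would otherwise leak into mask-standardization).
smooth_field <- function(mat, sigma_px) {
  k <- gauss_kernel(sigma_px)
  if (length(k) >= nrow(mat) || length(k) >= ncol(mat)) {
    k_max <- 2 * (min(nrow(mat), ncol(mat)) %/% 2) - 1
    mid <- (length(k) + 1) / 2
    half <- (k_max - 1) / 2
    k <- k[(mid - half):(mid + half)]
    k <- k / sum(k)
  }
  sm <- apply(mat, 2, function(v) stats::filter(v, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(v) stats::filter(v, k, circular = TRUE)))
  matrix(as.numeric(sm), nrow(mat), ncol(mat))
}

#' Per-pixel area in hectares
#'
#' The single area convention used throughout: a pixel of `res` degrees at
#' latitude `lat` covers (111.32 km * res) * (111.32 km * res * cos(lat))
#' * 100 ha, evaluated at the pixel centre.
#'
#' @param lat Latitude of the pixel centre, decimal degrees.
#' @param res Pixel size, degrees.
#' @return Area in hectares.
#' @export
pixel_area_ha <- function(lat, res) {
  (111.32 * res) * (111.32 * res * cos(lat * pi / 180)) * 100
}

#' Generate a spatially autocorrelated covariate grid
#'
#' Each continuous covariate is white noise smoothed with a Gaussian kernel
#' of correlation length `smoothness` (degrees), then standardized to mean 0
#' and sd 1 over the marsh mask. Categorical covariates are built by
#' quantile-slicing an additional smoothed field into integer classes. The
#' marsh mask itself is the top `mask_fraction` quantile of one more smoothed
#' field, giving contiguous marsh patches.
#'
#' @param spec A [grid_spec()].
#' @param names Character vector of covariate names (non-empty).
#' @param smoothness Correlation length in degrees (> 0).
#' @param categorical Named integer vector: covariate name -> number of
#'   classes. Names must be a subset of `names`.
#' @param mask_fraction Fraction of pixels inside the marsh mask.
#' @return An object of class `covariate_grid`: pixel-centre `lon`
#'   (increasing) and `lat` (decreasing from the north-west corner), a named
#'   list `data` of covariate matrices, the logical `mask`, and per-pixel
#'   `area_ha`.
#' @export
generate_covariate_grid <- function(spec, names, smoothness,
                                    categorical = integer(),
                                    mask_fraction = 0.4) {
  stopifnot(inherits(spec, "grid_spec"), length(names) > 0, smoothness > 0,
            mask_fraction > 0, mask_fraction <= 1)
  if (length(categorical) && !all(names(categorical) %in% names)) {
    stop("categorical covariates must be listed in 'names'")
  }
  res <- spec$resolution
  lon <- seq(spec$lon_min + res / 2, spec$lon_max - res / 2 + 1e-12, by = res)
  lat <- rev(seq(spec$lat_min + res / 2, spec$lat_max - res / 2 + 1e-12,
                 by = res))
  nr <- length(lat); nc <- length(lon)
  sigma_px <- smoothness / res

  with_seed(spec$seed, {
    mask_field <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                               max(sigma_px, 1))
    thr <- stats::quantile(mask_field, 1 - mask_fraction, names = FALSE)
    mask <- mask_field >= thr
    if (!any(mask)) stop("marsh mask is empty: no pixels survive masking")

    data <- list()
    for (nm in names) {
      f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma_px)
      if (nm %in% names(categorical)) {
        ncl <- categorical[[nm]]
        cuts <- stats::quantile(f[mask], probs = seq_len(ncl - 1) / ncl,
                                names = FALSE)
        data[[nm]] <- matrix(
          findInterval(f, cuts) + 1L, nr, nc
        )
      } else {
        mu <- mean(f[mask]); sd_ <- stats::sd(f[mask])
        if (sd_ == 0) sd_ <- 1
        data[[nm]] <- (f - mu) / sd_
      }
    }

    area <- matrix(rep(pixel_area_ha(lat, res), nc), nr, nc)
    structure(
      list(lon = lon, lat = lat, res = res, data = data,
           categorical = names(categorical)[names(categorical) %in% names],
           n_classes = categorical,
           mask = mask, area_ha = area, spec = spec),
      class = "covariate_grid"
    )
  })
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf("covariate_grid: %d x %d pixels (res %g deg), %d covariates\n",
              length(x$lat), length(x$lon), x$res, length(x$data)))
  cat(sprintf("  covariates: %s\n", paste(names(x$data), collapse = ", ")))
  cat(sprintf("  marsh mask: %d pixels (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# Row/column indices of the pixel containing each (lon, lat); NA outside grid.
grid_cell_index <- function(grid, lon, lat) {
  res <- grid$res
  col <- floor((lon - (grid$lon[1] - res / 2)) / res) + 1L
  row <- floor(((grid$lat[1] + res / 2) - lat) / res) + 1L
  col[col < 1 | col > length(grid$lon)] <- NA_integer_
  row[row < 1 | row > length(grid$lat)] <- NA_integer_
  data.frame(row = row, col = col)
}

#' True OCD field at a given depth
#'
#' Evaluates the noise-free generative model
#' OCD = intercept + sum(effects * covariate) + depth_effect * depth, clipped
#' at `params$floor`, over the marsh mask (NA outside).
#'
#' @param grid A [generate_covariate_grid()] result.
#' @param params An [ocd_params()].
#' @param depth Depth in cm (>= 0).
#' @return Matrix of OCD in g C cm^-3, NA outside the mask.
#' @export
generate_true_ocd <- function(grid, params, depth) {
  stopifnot(inherits(grid, "covariate_grid"), inherits(params, "ocd_params"),
            depth >= 0)
  missing_cov <- setdiff(names(params$effects), names(grid$data))
  if (length(missing_cov)) {
    stop("unknown covariate(s) in effects: ",
         paste(missing_cov, collapse = ", "))
  }
  ocd <- matrix(params$intercept + params$depth_effect * depth,
                length(grid$lat), length(grid$lon))
  for (nm in names(params$effects)) {
    ocd <- ocd + params$effects[[nm]] * grid$data[[nm]]
  }
  ocd <- pmax(ocd, params$floor)
  ocd[!grid$mask] <- NA_real_
  ocd
}

snap_to_mask <- function(grid, lon, lat) {
  idx <- which(grid$mask, arr.ind = TRUE)
  mlon <- grid$lon[idx[, 2]]
  mlat <- grid$lat[idx[, 1]]
  j <- which.min((mlon - lon)^2 + (mlat - lat)^2)
  c(mlon[j], mlat[j])
}

#' Sample clustered, depth-stratified soil cores
#'
#' Locations are drawn as `cluster_fraction` from Gaussian clusters centred
#' on random marsh pixels (snapped back onto the mask) plus a uniform
#' remainder over the mask. Each location is sampled at the design's
#' layer-centre depths; samples deeper than 30 cm are retained with
#' per-location probability `deep_retention`. Observed OCD is the generative
#' truth at the location's pixel and depth plus Normal(0, noise_sd) noise,
#' clipped at 0. Cluster membership is recorded as the `region` label
#' ("cluster_1", ..., or "background"), which downstream doubles as a
#' country/realm stand-in.
#'
#' @param grid A [generate_covariate_grid()] result.
#' @param params An [ocd_params()] truth definition.
#' @param design A [sampling_design()].
#' @return A data frame of cores with columns `location_id`, `lon`, `lat`,
#'   `depth_cm`, `ocd_gcm3`, `region`. Cluster centres are attached as the
#'   `"cluster_centres"` attribute.
#' @export
sample_cores <- function(grid, params, design) {
  stopifnot(inherits(grid, "covariate_grid"), inherits(params, "ocd_params"),
            inherits(design, "sampling_design"))
  masked <- which(grid$mask, arr.ind = TRUE)
  if (nrow(masked) < design$n_clusters) {
    stop("marsh mask too small to place ", design$n_clusters, " clusters")
  }

  with_seed(design$seed, {
    ctr_idx <- masked[sample.int(nrow(masked), design$n_clusters), ,
                      drop = FALSE]
    centres <- data.frame(
      cluster = paste0("cluster_", seq_len(design$n_clusters)),
      lon = grid$lon[ctr_idx[, 2]],
      lat = grid$lat[ctr_idx[, 1]]
    )

    n <- design$n_locations
    n_clustered <- round(design$cluster_fraction * n)
    assignment <- if (n_clustered > 0) {
      sample.int(design$n_clusters, n_clustered, replace = TRUE)
    } else integer()

    loc <- data.frame(lon = numeric(n), lat = numeric(n),
                      region = character(n))
    for (i in seq_len(n_clustered)) {
      ci <- assignment[i]
      ok <- FALSE
      for (try in 1:200) {
        cand_lon <- centres$lon[ci] + stats::rnorm(1, sd = design$cluster_sd)
        cand_lat <- centres$lat[ci] + stats::rnorm(1, sd = design$cluster_sd)
        cell <- grid_cell_index(grid, cand_lon, cand_lat)
        if (!is.na(cell$row) && !is.na(cell$col) &&
            grid$mask[cell$row, cell$col]) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        snapped <- snap_to_mask(grid, cand_lon, cand_lat)
        cand_lon <- snapped[1]; cand_lat <- snapped[2]
      }
      loc$lon[i] <- cand_lon; loc$lat[i] <- cand_lat
      loc$region[i] <- centres$cluster[ci]
    }
    n_bg <- n - n_clustered
    if (n_bg > 0) {
      pick <- masked[sample.int(nrow(masked), n_bg, replace = TRUE), ,
                     drop = FALSE]
      jitter <- matrix(stats::runif(2 * n_bg, -grid$res / 2, grid$res / 2),
                       ncol = 2)
      loc$lon[(n_clustered + 1):n] <- grid$lon[pick[, 2]] + jitter[, 1]
      loc$lat[(n_clustered + 1):n] <- grid$lat[pick[, 1]] + jitter[, 2]
      loc$region[(n_clustered + 1):n] <- "background"
    }

    deep <- design$depth_grid > 30
    keep_deep <- stats::runif(n) < design$deep_retention
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      depths <- design$depth_grid[!deep | keep_deep[i]]
      cell <- grid_cell_index(grid, loc$lon[i], loc$lat[i])
      ocd_true <- vapply(depths, function(d) {
        params$intercept + params$depth_effect * d +
          sum(vapply(names(params$effects), function(nm) {
            params$effects[[nm]] * grid$data[[nm]][cell$row, cell$col]
          }, numeric(1)))
      }, numeric(1))
      ocd_true <- pmax(ocd_true, params$floor)
      noise <- if (params$noise_sd > 0) {
        stats::rnorm(length(depths), sd = params$noise_sd)
      } else 0
      rows[[i]] <- data.frame(
        location_id = sprintf("loc_%04d", i),
        lon = loc$lon[i], lat = loc$lat[i],
        depth_cm = depths,
        ocd_gcm3 = pmax(ocd_true + noise, 0),
        region = loc$region[i]
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "cluster_centres") <- centres
    out
  })
}

#' Region raster from cluster centres
#'
#' Assigns every marsh pixel to the nearest cluster centre (great-circle
#' distance), yielding the region stand-ins used for aggregation.
#'
#' @param grid A covariate grid.
#' @param centres Data frame with `cluster`, `lon`, `lat` (as attached by
#'   [sample_cores()]).
#' @return Character matrix of region labels, NA outside the mask.
#' @export
region_raster <- function(grid, centres) {
  stopifnot(inherits(grid, "covariate_grid"), nrow(centres) > 0)
  out <- matrix(NA_character_, length(grid$lat), length(grid$lon))
  masked <- which(grid$mask, arr.ind = TRUE)
  d <- haversine_matrix(grid$lon[masked[, 2]], grid$lat[masked[, 1]],
                        centres$lon, centres$lat)
  nearest <- apply(d, 1, which.min)
  out[masked] <- centres$cluster[nearest]
  out
}
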
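#' Great-circle distance between points (haversine)
#'
#' Distances on the WGS84 sphere with radius 6371 km. Inputs are recycled;
#' coordinates are decimal degrees (lon, lat).
#'
#' @param lon1,lat1,lon2,lat2 Numeric vectors of coordinates in decimal
#'   degrees.
#' @return Numeric vector of distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix
#'
#' @param lon,lat Coordinate vectors (rows of the result).
#' @param lon2,lat2 Optional second set (columns); defaults to the first set.
#' @return Matrix of distances in km, `length(lon)` x `length(lon2)`.
#' @export
haversine_matrix <- function(lon, lat, lon2 = lon, lat2 = lat) {
  n <- length(lon)
  m <- length(lon2)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    out[, j] <- haversine_km(lon, lat, lon2[j], lat2[j])
  }
  out
}

#' Nearest-neighbour great-circle distances
#'
#' For each point in `from`, the distance (km) to the nearest point in `to`.
#' When the two sets are identical objects, self-matches (zero distance to
#' oneself) are excluded if `exclude_self = TRUE`.
#'
#' @param from,to Data frames with `lon` and `lat` columns.
#' @param exclude_self Exclude the i-th `to` point when scanning the i-th
#'   `from` point (only meaningful when the sets coincide row-by-row).
#' @return Sorted numeric vector of nearest-neighbour distances (km).
#' @export
nnd_ecdf <- function(from, to, exclude_self = FALSE) {
  stopifnot(nrow(from) > 0, nrow(to) > 0)
  d <- haversine_matrix(from$lon, from$lat, to$lon, to$lat)
  if (exclude_self) {
    if (nrow(from) != nrow(to)) {
      stop("exclude_self requires 'from' and 'to' to be the same point set")
    }
    diag(d) <- Inf
  }
  sort(apply(d, 1, min))
}

#' Wasserstein-1 distance between two empirical distributions
#'
#' The area between the two ECDFs, computed exactly on the pooled sorted
#' sample. This is the matching criterion used to score candidate fold
#' configurations against prediction-to-training distance distributions.
#'
#' @param x,y Numeric samples (need not be the same size).
#' @return Non-negative scalar in the units of `x` and `y`.
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  pooled <- sort(unique(c(x, y)))
  if (length(pooled) == 1) return(0)
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  widths <- diff(pooled)
  sum(abs(fx - fy)[-length(pooled)] * widths)
}
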
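# Plain-text I/O: rasters as ESRI ASCII grids (centre-registered, nodata
# outside the mask), core tables as CSV with a pinned schema, and JSON
# sidecars for thresholds, calibrations and manifests.

CORES_SCHEMA <- c("location_id", "lon", "lat", "depth_cm", "ocd_gcm3",
                  "region")

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param mat Numeric matrix (row 1 = northernmost row).
#' @param grid The `covariate_grid` supplying the georeferencing.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Nodata sentinel written for NA cells.
#' @export
write_ascii_grid <- function(mat, grid, path, nodata = -9999) {
  stopifnot(identical(dim(mat), dim(grid$mask)))
  res <- grid$res
  header <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", grid$lon[1] - res / 2),
    sprintf("yllcorner %.10g", grid$lat[length(grid$lat)] - res / 2),
    sprintf("cellsize %.10g", res),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(mat, 1, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return List with `values` (matrix, NA at nodata), `xllcorner`,
#'   `yllcorner`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(ln, " +")[[1]][2])
  }
  ncols <- get("ncols"); nrows <- get("nrows")
  nodata <- get("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  mat <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  mat[mat == nodata] <- NA_real_
  list(values = mat, xllcorner = get("xllcorner"),
       yllcorner = get("yllcorner"), cellsize = get("cellsize"))
}

#' Write a core table as CSV (pinned schema)
#'
#' @param cores Core data frame with columns `location_id, lon, lat,
#'   depth_cm, ocd_gcm3, region`.
#' @param path Output path.
#' @export
write_cores_csv <- function(cores, path) {
  missing_cols <- setdiff(CORES_SCHEMA, names(cores))
  if (length(missing_cols)) {
    stop("core table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(cores[, CORES_SCHEMA], path, row.names = FALSE)
  invisible(path)
}

#' Read a core table CSV, validating the schema
#'
#' @param path CSV path.
#' @return Data frame with the pinned core schema.
#' @export
read_cores_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CORES_SCHEMA, names(out))
  if (length(missing_cols)) {
    stop("core CSV ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out
}

write_sidecar_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
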
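# Layer stocks: per-pixel OCD predictions at the standard depths (0, 30,
# 100 cm) integrated to SOC stocks by the trapezoid rule, then masked by the
# area of applicability.

#' Table of marsh pixels with covariates
#'
#' One row per pixel inside the marsh mask: grid indices, centre coordinates,
#' area (ha) and every covariate value — the prediction frame for the fitted
#' model and the DI machinery.
#'
#' @param grid A `covariate_grid`.
#' @return Data frame with `row`, `col`, `lon`, `lat`, `area_ha` and one
#'   column per covariate.
#' @export
pixel_table <- function(grid) {
  stopifnot(inherits(grid, "covariate_grid"))
  idx <- which(grid$mask, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
                    area_ha = grid$area_ha[idx])
  for (nm in names(grid$data)) out[[nm]] <- grid$data[[nm]][idx]
  out
}

#' Trapezoidal layer-stock integration
#'
#' SOC stock of a layer from the OCD at its upper and lower bounding depths:
#' mean of the two densities (g C cm^-3) times layer thickness (cm) times
#' 100, giving Mg C ha^-1. The factor 100 converts g C cm^-2 to Mg C ha^-1
#' (1 g cm^-2 = 100 Mg ha^-1).
#'
#' @param ocd_top,ocd_bottom OCD at the layer bounds, g C cm^-3 (>= 0).
#' @param thickness Layer thickness, cm (30 and 70 for the standard layers).
#' @return Stock in Mg C ha^-1.
#' @export
integrate_stock <- function(ocd_top, ocd_bottom, thickness) {
  if (any(ocd_top < 0, na.rm = TRUE) || any(ocd_bottom < 0, na.rm = TRUE)) {
    stop("OCD inputs must be non-negative")
  }
  stopifnot(all(thickness > 0))
  (ocd_top + ocd_bottom) / 2 * thickness * 100
}

#' Predict per-pixel layer stocks (pre-mask)
#'
#' Predicts OCD at every depth bounding the requested layers for every marsh
#' pixel, in chunks of `chunk_size` pixels (output is independent of
#' chunking), then integrates each layer with [integrate_stock()].
#'
#' @param model A `fitted_model`.
#' @param grid A `covariate_grid` carrying all model covariates.
#' @param layers List of length-2 numeric `(top, bottom)` depth pairs in cm;
#'   default the standard 0–30 and 30–100 cm layers.
#' @param chunk_size Pixels per prediction chunk.
#' @return A `layer_stock_map`: per layer a stock matrix (Mg C ha^-1, NA off
#'   mask) plus the OCD surfaces at each standard depth.
#' @export
predict_layer_stocks <- function(model, grid,
                                 layers = list(c(0, 30), c(30, 100)),
                                 chunk_size = 5000) {
  px <- pixel_table(grid)
  depths <- sort(unique(unlist(layers)))
  nr <- length(grid$lat); nc <- length(grid$lon)
  ocd <- list()
  chunks <- split(seq_len(nrow(px)),
                  ceiling(seq_len(nrow(px)) / max(1, chunk_size)))
  for (d in depths) {
    surf <- matrix(NA_real_, nr, nc)
    for (ch in chunks) {
      rows <- px[ch, , drop = FALSE]
      surf[cbind(rows$row, rows$col)] <- predict_ocd(model, rows, depth = d)
    }
    ocd[[as.character(d)]] <- surf
  }
  layer_list <- list()
  for (ly in layers) {
    key <- sprintf("%g-%g", ly[1], ly[2])
    stock <- integrate_stock(ocd[[as.character(ly[1])]],
                             ocd[[as.character(ly[2])]],
                             ly[2] - ly[1])
    layer_list[[key]] <- list(top = ly[1], bottom = ly[2], stock = stock,
                              expected_error = NULL, aoa = NULL,
                              stock_premask = stock, error_premask = NULL)
  }
  structure(
    list(grid = grid, layers = layer_list, ocd_surfaces = ocd,
         masked = FALSE),
    class = "layer_stock_map"
  )
}

#' Attach expected-error surfaces to a stock map
#'
#' @param stock_map A `layer_stock_map`.
#' @param error_surfaces Named list (layer key, e.g. "0-30") of expected-error
#'   matrices in Mg C ha^-1.
#' @return The stock map with errors attached (pre-mask copies kept).
#' @export
attach_expected_error <- function(stock_map, error_surfaces) {
  for (key in names(error_surfaces)) {
    if (!key %in% names(stock_map$layers)) stop("unknown layer: ", key)
    stock_map$layers[[key]]$expected_error <- error_surfaces[[key]]
    stock_map$layers[[key]]$error_premask <- error_surfaces[[key]]
  }
  stock_map
}

#' Apply AOA masks to a stock map
#'
#' Pixels outside a layer's AOA are set to NA in that layer's final stock and
#' expected-error rasters. Pre-mask rasters are retained unchanged; masking
#' never alters surviving pixel values.
#'
#' @param stock_map A `layer_stock_map`.
#' @param aoa_masks Named list (layer key) of logical AOA matrices from
#'   [aoa_mask()].
#' @return The masked `layer_stock_map` (`masked = TRUE`).
#' @export
apply_aoa <- function(stock_map, aoa_masks) {
  for (key in names(aoa_masks)) {
    if (!key %in% names(stock_map$layers)) stop("unknown layer: ", key)
    m <- aoa_masks[[key]]
    ly <- stock_map$layers[[key]]
    if (!identical(dim(m), dim(ly$stock))) {
      stop("AOA mask dimensions do not match the stock grid for layer ", key)
    }
    outside <- !m
    outside[is.na(outside)] <- TRUE
    ly$stock[outside] <- NA_real_
    if (!is.null(ly$expected_error)) ly$expected_error[outside] <- NA_real_
    ly$aoa <- m
    stock_map$layers[[key]] <- ly
  }
  stock_map$masked <- TRUE
  stock_map
}

#' @export
print.layer_stock_map <- function(x, ...) {
  cat(sprintf("layer_stock_map: %d layers over %d marsh pixels%s\n",
              length(x$layers), sum(x$grid$mask),
              if (x$masked) " (AOA-masked)" else " (pre-mask)"))
  for (key in names(x$layers)) {
    s <- x$layers[[key]]$stock
    cat(sprintf("  %s cm: mean %.1f Mg C ha^-1 over %d pixels\n", key,
                mean(s, na.rm = TRUE), sum(!is.na(s))))
  }
  invisible(x)
}
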
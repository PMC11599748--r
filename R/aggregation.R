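# Area-weighted aggregation of the per-pixel stock maps: 2-degree cells,
# user-supplied regions (realm/country stand-ins), global totals, AOA
# coverage fractions, and the bivariate prediction/error cell classes.

# Long pixel table: one row per marsh pixel with per-layer final and pre-mask
# stock/error and AOA status.
stock_pixel_table <- function(stock_map, region_labels = NULL) {
  grid <- stock_map$grid
  idx <- which(grid$mask, arr.ind = TRUE)
  out <- data.frame(lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
                    area_ha = grid$area_ha[idx])
  for (key in names(stock_map$layers)) {
    ly <- stock_map$layers[[key]]
    safe <- gsub("-", "_", key)
    out[[paste0("stock_", safe)]] <- ly$stock[idx]
    out[[paste0("stock_premask_", safe)]] <- ly$stock_premask[idx]
    if (!is.null(ly$expected_error)) {
      out[[paste0("error_", safe)]] <- ly$expected_error[idx]
      out[[paste0("error_premask_", safe)]] <- ly$error_premask[idx]
    }
    out[[paste0("aoa_", safe)]] <- if (!is.null(ly$aoa)) {
      as.logical(ly$aoa[idx])
    } else TRUE
  }
  if (!is.null(region_labels)) {
    if (!identical(dim(region_labels), dim(grid$mask))) {
      stop("region label raster does not match the grid")
    }
    region <- region_labels[idx]
    region[is.na(region)] <- "unassigned"
    out$region <- region
  }
  out
}

weighted_mean_na <- function(x, w) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

layer_keys <- function(stock_map) gsub("-", "_", names(stock_map$layers))

#' Aggregate stocks to square cells
#'
#' Aggregates the per-pixel map to `cell_size`-degree cells: per layer, the
#' area-weighted mean final stock and expected error over inside-AOA pixels,
#' the total stock (Tg C) of those pixels, the percent of pixels inside the
#' AOA, and the area-weighted pre-mask means used for the bivariate
#' prediction/error product. Cells whose layer has 0% inside-AOA pixels are
#' flagged `displayed = FALSE` for that layer.
#'
#' @param stock_map A `layer_stock_map` (typically AOA-masked).
#' @param cell_size Cell size in degrees (default 2).
#' @return Data frame with one row per non-empty cell.
#' @export
aggregate_cells <- function(stock_map, cell_size = 2) {
  px <- stock_pixel_table(stock_map)
  px$cell_lon <- floor(px$lon / cell_size) * cell_size
  px$cell_lat <- floor(px$lat / cell_size) * cell_size
  px$cell_id <- sprintf("%g_%g", px$cell_lon, px$cell_lat)
  keys <- layer_keys(stock_map)
  cells <- split(px, px$cell_id)
  out <- lapply(cells, function(cc) {
    row <- data.frame(cell_id = cc$cell_id[1], cell_lon = cc$cell_lon[1],
                      cell_lat = cc$cell_lat[1], n_pixels = nrow(cc),
                      area_ha = sum(cc$area_ha))
    for (key in keys) {
      s <- cc[[paste0("stock_", key)]]
      inside <- !is.na(s)
      row[[paste0("mean_stock_", key)]] <- weighted_mean_na(s, cc$area_ha)
      row[[paste0("total_tg_", key)]] <-
        sum(s[inside] * cc$area_ha[inside]) / 1e6
      row[[paste0("pct_aoa_", key)]] <- 100 * mean(inside)
      row[[paste0("displayed_", key)]] <- any(inside)
      row[[paste0("mean_stock_premask_", key)]] <-
        weighted_mean_na(cc[[paste0("stock_premask_", key)]], cc$area_ha)
      err_pm <- cc[[paste0("error_premask_", key)]]
      if (!is.null(err_pm)) {
        row[[paste0("mean_error_premask_", key)]] <-
          weighted_mean_na(err_pm, cc$area_ha)
        row[[paste0("mean_error_", key)]] <-
          weighted_mean_na(cc[[paste0("error_", key)]], cc$area_ha)
      }
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_lat, out$cell_lon), ]
}

#' Region and global summaries
#'
#' Area-weighted per-region summaries over inside-AOA pixels: marsh area,
#' mean stock and mean expected error per layer, total stock in Tg C
#' (Pg = Tg / 1000), and percent of pixels inside the AOA per layer. A
#' `global` row summarizes all pixels; unlabeled pixels are reported as
#' `unassigned`. The global 0–100 cm per-hectare mean is the sum of the two
#' layer means computed on the pixels inside both layers' AOAs (the
#' intersection set), reported in the `mean_stock_0_100_intersect` column.
#'
#' @param stock_map A `layer_stock_map`.
#' @param region_labels Character matrix of region labels (NA = unassigned),
#'   e.g. from [region_raster()].
#' @param area_weighted Use pixel-area weighting for means (default TRUE);
#'   FALSE gives simple pixel means.
#' @return Data frame with one row per region plus `global`.
#' @export
summarize_regions <- function(stock_map, region_labels,
                              area_weighted = TRUE) {
  px <- stock_pixel_table(stock_map, region_labels)
  keys <- layer_keys(stock_map)
  if (!area_weighted) px$area_ha_w <- 1 else px$area_ha_w <- px$area_ha

  summarize_one <- function(cc, label) {
    row <- data.frame(region = label, n_pixels = nrow(cc),
                      area_ha = sum(cc$area_ha))
    both_inside <- rep(TRUE, nrow(cc))
    for (key in keys) {
      s <- cc[[paste0("stock_", key)]]
      inside <- !is.na(s)
      both_inside <- both_inside & inside
      row[[paste0("mean_stock_", key)]] <- weighted_mean_na(s, cc$area_ha_w)
      row[[paste0("total_tg_", key)]] <-
        sum(s[inside] * cc$area_ha[inside]) / 1e6
      row[[paste0("pct_aoa_", key)]] <- 100 * mean(inside)
      err <- cc[[paste0("error_", key)]]
      row[[paste0("mean_error_", key)]] <- if (!is.null(err)) {
        weighted_mean_na(err, cc$area_ha_w)
      } else NA_real_
    }
    total <- 0
    for (key in keys) total <- total + row[[paste0("total_tg_", key)]]
    row$total_tg <- total
    row$total_pg <- total / 1000
    if (any(both_inside)) {
      m <- 0
      for (key in keys) {
        m <- m + weighted_mean_na(
          ifelse(both_inside, cc[[paste0("stock_", key)]], NA_real_),
          cc$area_ha_w)
      }
      row$mean_stock_0_100_intersect <- m
    } else {
      row$mean_stock_0_100_intersect <- NA_real_
    }
    row
  }

  parts <- split(px, px$region)
  out <- do.call(rbind, c(
    lapply(names(parts), function(r) summarize_one(parts[[r]], r)),
    list(summarize_one(px, "global"))
  ))
  rownames(out) <- NULL
  out
}

#' Bivariate prediction/error classification of cells
#'
#' Classifies aggregated cells into the four combinations of low/high
#' prediction and low/high expected error, on the pre-mask cell means (the
#' sampling-prioritisation product). Default thresholds are the medians
#' across cells; they are echoed in the result's attributes.
#'
#' @param cell_table Output of [aggregate_cells()].
#' @param layer Layer key, e.g. "0_30".
#' @param pred_threshold,err_threshold Optional explicit thresholds; default
#'   medians.
#' @return The cell table with `pred_class` and `error_class` columns
#'   ("low"/"high"); thresholds in attributes `pred_threshold` and
#'   `err_threshold`.
#' @export
bivariate_classify <- function(cell_table, layer = "0_30",
                               pred_threshold = NULL, err_threshold = NULL) {
  pcol <- paste0("mean_stock_premask_", layer)
  ecol <- paste0("mean_error_premask_", layer)
  if (!pcol %in% names(cell_table) || !ecol %in% names(cell_table)) {
    stop("cell table lacks pre-mask prediction/error columns for layer ",
         layer)
  }
  p <- cell_table[[pcol]]; e <- cell_table[[ecol]]
  if (is.null(pred_threshold)) pred_threshold <- stats::median(p, na.rm = TRUE)
  if (is.null(err_threshold)) err_threshold <- stats::median(e, na.rm = TRUE)
  if (length(unique(stats::na.omit(p))) <= 1 ||
      length(unique(stats::na.omit(e))) <= 1) {
    warning("prediction or error values are all equal; single class")
  }
  cell_table$pred_class <- ifelse(p > pred_threshold, "high", "low")
  cell_table$error_class <- ifelse(e > err_threshold, "high", "low")
  attr(cell_table, "pred_threshold") <- pred_threshold
  attr(cell_table, "err_threshold") <- err_threshold
  cell_table
}
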
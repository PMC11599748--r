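# End-to-end orchestration: simulate (or load) -> training table -> spatial
# CV folds -> (optional tuning) -> fit + cross-validate -> DI / AOA / error
# calibration -> layer stocks -> aggregation. One top-level seed feeds named
# per-stage substreams; each stage caches its result so a run can resume
# after deleting downstream outputs only.

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offset)
}

#' Default pipeline configuration
#'
#' The default configuration reproduces the study conditions on a synthetic
#' landscape: three dense sampling clusters holding 85% of core locations,
#' depth-stratified sampling with 35% retention below 30 cm, k = 5 distance-
#' matched folds, and the pinned forest settings (mtry 3, node size 5, 300
#' trees). Sizes (grid, core count, prediction points) are desk-scale.
#'
#' @param seed Top-level integer seed.
#' @param out_dir Output directory.
#' @return A nested configuration list consumed by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("marshstock_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    grid = list(lon_min = 0, lon_max = 1.28, lat_min = 40, lat_max = 41.28,
                resolution = 0.02,
                covariates = c("elevation", "ndvi_median", "tidal_amplitude",
                               "max_temperature", "coastal_type"),
                categorical = c(coastal_type = 4L),
                smoothness = 0.1, mask_fraction = 0.4),
    truth = list(intercept = 0.03,
                 effects = c(elevation = -0.008, ndvi_median = 0.006,
                             tidal_amplitude = 0.004, max_temperature = 0.002),
                 depth_effect = -5e-5, noise_sd = 0.004),
    design = list(n_locations = 300L, n_clusters = 3L,
                  cluster_fraction = 0.85, cluster_sd = 0.05,
                  depth_grid = c(5, 15, 25, 45, 75, 95),
                  deep_retention = 0.35),
    cv = list(k = 5L, strategy = "knndm", n_prediction_points = 1000L),
    model = list(mtry = 3L, min_node = 5L, n_trees = 300L, tune = FALSE),
    calibration = list(window_fraction = 0.1, min_window = 20L),
    layers = list(c(0, 30), c(30, 100)),
    cell_size = 0.32
  )
}

run_stage <- function(name, out_dir, output_files, resume, fun) {
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(cache_dir, paste0(name, ".rds"))
  if (resume && file.exists(cache) &&
      all(file.exists(file.path(out_dir, output_files)))) {
    message("stage ", name, ": reusing cached result")
    return(readRDS(cache))
  }
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  saveRDS(res, cache)
  res
}

#' Run the full SOC-stock pipeline
#'
#' Executes every stage on a synthetic landscape (or user-supplied core CSV
#' and covariate grid), writing all products as plain-text rasters, CSV
#' tables and JSON sidecars, plus a manifest of output files with MD5 hashes.
#' Reruns with the same config and seed are bit-identical; with
#' `resume = TRUE`, stages whose cache and outputs survive are reused.
#'
#' @param config Configuration list, see [default_config()]. Supply
#'   `config$cores` (a core data frame) and `config$grid_object` (a
#'   `covariate_grid`) to skip simulation.
#' @param resume Reuse cached stage results when their outputs still exist.
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
run_pipeline <- function(config = default_config(), resume = FALSE) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## 1 - landscape (simulate or adopt supplied inputs)
  sim <- run_stage("simulate", out_dir, c("cores.csv"), resume, function() {
    if (!is.null(config$cores) && !is.null(config$grid_object)) {
      grid <- config$grid_object
      cores <- config$cores
      centres <- attr(cores, "cluster_centres")
      truth <- NULL
    } else {
      g <- config$grid
      spec <- grid_spec(g$lon_min, g$lon_max, g$lat_min, g$lat_max,
                        g$resolution, seed = stage_seed(seed, 1))
      grid <- generate_covariate_grid(spec, g$covariates, g$smoothness,
                                      categorical = g$categorical,
                                      mask_fraction = g$mask_fraction)
      t <- config$truth
      truth <- ocd_params(t$intercept, t$effects, t$depth_effect, t$noise_sd)
      d <- config$design
      design <- sampling_design(d$n_locations, d$n_clusters,
                                d$cluster_fraction, d$cluster_sd,
                                d$depth_grid, d$deep_retention,
                                seed = stage_seed(seed, 2))
      cores <- sample_cores(grid, truth, design)
      centres <- attr(cores, "cluster_centres")
    }
    regions <- if (!is.null(centres)) region_raster(grid, centres)
    write_cores_csv(cores, file.path(out_dir, "cores.csv"))
    for (nm in names(grid$data)) {
      write_ascii_grid(grid$data[[nm]], grid,
                       file.path(out_dir, paste0("covariate_", nm, ".asc")))
    }
    list(grid = grid, cores = cores, regions = regions, truth = truth)
  })

  ## 2 - training table
  training <- run_stage("training", out_dir, "training_matrix.csv", resume,
                        function() {
    cores <- filter_sites(sim$cores, mask = sim$grid)
    mat <- extract_covariates(cores, sim$grid)
    utils::write.csv(as.data.frame(mat),
                     file.path(out_dir, "training_matrix.csv"),
                     row.names = FALSE)
    screen <- collinearity_screen(mat)
    utils::write.csv(screen, file.path(out_dir, "collinearity.csv"),
                     row.names = FALSE)
    list(matrix = mat, screen = screen)
  })

  ## 3 - spatial CV folds
  folds <- run_stage("folds", out_dir, "folds.csv", resume, function() {
    pred_pts <- sample_prediction_points(sim$grid,
                                         n = config$cv$n_prediction_points,
                                         seed = stage_seed(seed, 3))
    fa <- if (config$cv$strategy == "knndm") {
      knndm_folds(training$matrix, pred_pts, k = config$cv$k)
    } else {
      random_folds(training$matrix, k = config$cv$k,
                   seed = stage_seed(seed, 4),
                   prediction_points = pred_pts)
    }
    utils::write.csv(fa$folds, file.path(out_dir, "folds.csv"),
                     row.names = FALSE)
    list(assignment = fa, prediction_points = pred_pts)
  })

  ## 4 - model spec (optionally tuned) + fit + cross-validation
  model <- run_stage("model", out_dir, "cv_samples.csv", resume, function() {
    m <- config$model
    spec <- if (isTRUE(m$tune)) {
      tuned <- tune_ocd_model(training$matrix, folds$assignment,
                              seed = stage_seed(seed, 5))
      utils::write.csv(tuned$results, file.path(out_dir, "tuning.csv"),
                       row.names = FALSE)
      tuned$selected
    } else {
      model_spec(m$mtry, m$min_node, m$n_trees, seed = stage_seed(seed, 5))
    }
    cv <- cross_validate(training$matrix, folds$assignment, spec)
    utils::write.csv(cv$samples, file.path(out_dir, "cv_samples.csv"),
                     row.names = FALSE)
    fit <- fit_ocd_model(training$matrix, spec)
    utils::write.csv(
      data.frame(predictor = names(fit$importance_norm),
                 importance = unname(fit$importance),
                 importance_norm = unname(fit$importance_norm)),
      file.path(out_dir, "importance.csv"), row.names = FALSE)
    list(spec = spec, fit = fit, cv = cv)
  })

  ## 5 - uncertainty: DI space, threshold, error calibration
  unc <- run_stage("uncertainty", out_dir, "aoa_calibration.json", resume,
                   function() {
    space <- build_space(model$fit, training$matrix, folds$assignment)
    tdi <- training_di(space, training$matrix)
    threshold <- aoa_threshold(tdi)
    em <- calibrate_error(model$cv, tdi,
                          window_fraction = config$calibration$window_fraction,
                          min_window = config$calibration$min_window)
    write_sidecar_json(
      list(aoa_threshold = threshold,
           calibration = list(di = em$di, rmse = em$rmse, window = em$window,
                              constraint = em$constraint),
           cv = list(r2 = model$cv$r2, rmse = model$cv$rmse)),
      file.path(out_dir, "aoa_calibration.json"))
    list(space = space, training_di = tdi, threshold = threshold,
         error_model = em)
  })

  ## 6 - per-pixel stocks, DI surfaces, expected error, AOA masking
  stocks <- run_stage("stocks", out_dir, "stock_final_0_30.asc", resume,
                      function() {
    smap <- predict_layer_stocks(model$fit, sim$grid, layers = config$layers)
    depths <- sort(unique(unlist(config$layers)))
    di_surfaces <- lapply(depths, function(d) di_surface(sim$grid, unc$space, d))
    names(di_surfaces) <- as.character(depths)
    err <- list(); aoa <- list()
    for (ly in config$layers) {
      key <- sprintf("%g-%g", ly[1], ly[2])
      err[[key]] <- expected_error_surface(sim$grid, unc$space,
                                           unc$error_model, ly,
                                           di_at_depths = di_surfaces)
      aoa[[key]] <- aoa_mask(di_surfaces, unc$threshold, ly)
    }
    smap <- attach_expected_error(smap, err)
    smap <- apply_aoa(smap, aoa)
    for (key in names(smap$layers)) {
      safe <- gsub("-", "_", key)
      ly <- smap$layers[[key]]
      write_ascii_grid(ly$stock_premask, sim$grid,
                       file.path(out_dir, paste0("stock_premask_", safe, ".asc")))
      write_ascii_grid(ly$stock, sim$grid,
                       file.path(out_dir, paste0("stock_final_", safe, ".asc")))
      write_ascii_grid(ly$expected_error, sim$grid,
                       file.path(out_dir, paste0("error_final_", safe, ".asc")))
      write_ascii_grid(ly$error_premask, sim$grid,
                       file.path(out_dir, paste0("error_premask_", safe, ".asc")))
      aoa_num <- ly$aoa * 1
      aoa_num[!sim$grid$mask] <- NA_real_
      write_ascii_grid(aoa_num, sim$grid,
                       file.path(out_dir, paste0("aoa_", safe, ".asc")))
    }
    for (d in names(di_surfaces)) {
      write_ascii_grid(di_surfaces[[d]], sim$grid,
                       file.path(out_dir, paste0("di_depth_", d, ".asc")))
    }
    list(map = smap, di_surfaces = di_surfaces)
  })

  ## 7 - aggregation
  agg <- run_stage("aggregate", out_dir, "regions.csv", resume, function() {
    cells <- aggregate_cells(stocks$map, cell_size = config$cell_size)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    regions <- summarize_regions(stocks$map, sim$regions)
    utils::write.csv(regions, file.path(out_dir, "regions.csv"),
                     row.names = FALSE)
    biv <- bivariate_classify(cells)
    utils::write.csv(biv, file.path(out_dir, "bivariate.csv"),
                     row.names = FALSE)
    list(cells = cells, regions = regions, bivariate = biv)
  })

  ## manifest
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- files[!grepl("^cache/", files) & files != "manifest.json"]
  manifest <- list(
    config = config[setdiff(names(config), c("cores", "grid_object"))],
    seed = seed,
    outputs = lapply(files, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  write_sidecar_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(landscape = sim, training = training, folds = folds,
                 model = model, uncertainty = unc, stocks = stocks,
                 aggregation = agg, manifest = manifest, out_dir = out_dir))
}
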
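#' Default pipeline configuration
#'
#' All stage parameters with the published analysis values as defaults:
#' stabilization (4 pyramid levels, iterations 100/50/10/1), variation map
#' (Gaussian sigma 1 px, FIR kernel (0.5, -1, 0.5), 7x7 median), vessel
#' size gates (0.1% and 10% of the frame), trafficking (6 s background
#' window, 7.5 px DoG radius, quality threshold 1.6, 20 px max link,
#' per-window thresholds), phenotyping (95% variance retained) and the
#' 1.33 px/um imaging scale.
#'
#' @param ... named overrides of the defaults, using the same nesting as
#'   the returned list (e.g. `vessels = list(closing_radius_px = 2)`).
#'   Unknown keys are rejected.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    pixel_per_um = 1.33,
    frame_interval_s = 0.2,
    stabilization = list(
      enabled = TRUE, transform = "rigid", blank_fraction = 0.75,
      pyramid_levels = 4L, iterations_per_level = c(100L, 50L, 10L, 1L),
      smoothing_sigma = 1.0),
    vessels = list(
      enabled = TRUE, gaussian_sigma_px = 1, fir_kernel = c(0.5, -1, 0.5),
      median_window_px = 7L, min_area_frac = 0.001, max_area_frac = 0.10,
      closing_radius_px = 3L, frame_stride = 1L),
    trafficking = list(
      enabled = TRUE, window_s = 6, radius_px = 7.5, quality_threshold = 1.6,
      quality_scale = 4, max_link_px = 20,
      displacement_px = c(20.5, 22.5, 22.5),
      consistency_deg = c(58, 58, 58),
      quality = c(1.6, 1.65, 1.75),
      windows_s = c(0.6, 0.8, 1.0)),
    segmentation = list(enabled = FALSE, input_size_px = 256L),
    phenotyping = list(enabled = TRUE, n_clusters = "auto",
                       variance_retained = 0.95),
    response = list(enabled = FALSE, mode = "specificity_first",
                    max_features = 2L, cutoff = 0.5),
    log_level = "info")
  overrides <- list(...)
  structure(merge_config(cfg, overrides, path = ""), class = "pipeline_config")
}

merge_config <- function(base, overrides, path) {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(overrides[[key]]))
      base[[key]] <- merge_config(base[[key]], overrides[[key]], full)
    else base[[key]] <- overrides[[key]]
  }
  base
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config].
#' @param path JSON file path.
#' @return `path` invisibly (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the TiME quantification pipeline on a set of videos
#'
#' Per video: (optional) two-step stabilization, temporal-variation vessel
#' segmentation with metrics, and trafficking counts per temporal window.
#' Results are merged with a manual feature table when one is supplied,
#' and phenotyping / response modeling run on that table when enabled.
#'
#' @param videos list of [video_stack] objects or TIFF paths.
#' @param feature_table optional [feature_table] (or CSV path) of manual
#'   grades for phenotyping / response modeling.
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, the per-lesion CSV and a
#'   JSON run report are written there.
#' @return List with `quantification` (one row per video: vessel count,
#'   area fraction, mean/max diameter, per-window trafficking counts,
#'   residual motion), and optional `phenotype_model`, `response_models`.
#' @export
run_pipeline <- function(videos, feature_table = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(videos)) videos <- as.list(videos)
  thr <- trafficking_thresholds(config$pixel_per_um)
  thr$displacement_px <- config$trafficking$displacement_px
  thr$consistency_deg <- config$trafficking$consistency_deg
  thr$quality <- config$trafficking$quality
  thr$windows_s <- config$trafficking$windows_s

  rows <- lapply(seq_along(videos), function(i) {
    v <- videos[[i]]
    if (is.character(v)) {
      if (!file.exists(v)) stop("unreadable input: ", v)
      v <- read_video_tiff(v, frame_interval_s = config$frame_interval_s,
                           pixel_per_um = config$pixel_per_um)
    }
    stage <- "stabilization"
    res <- tryCatch({
      residual <- NA_real_
      if (config$stabilization$enabled && n_frames(v) >= 2) {
        pre <- prealign_linear(v, transform = config$stabilization$transform)
        rect <- auto_crop(pre$video, config$stabilization$blank_fraction)
        v <- crop_video(pre$video, rect)
        st <- stabilize_nonlinear(
          v, pyramid_levels = config$stabilization$pyramid_levels,
          iterations_per_level = config$stabilization$iterations_per_level,
          smoothing_sigma = config$stabilization$smoothing_sigma,
          blank_fraction = config$stabilization$blank_fraction)
        v <- st$stabilized
        residual <- st$residual_motion_score
      }
      stage <- "vessels"
      vm <- variation_map(v, config$vessels$gaussian_sigma_px,
                          config$vessels$fir_kernel,
                          config$vessels$median_window_px,
                          config$vessels$frame_stride)
      mask <- segment_vessels(vm, config$vessels$min_area_frac,
                              config$vessels$max_area_frac,
                              config$vessels$closing_radius_px)
      met <- vessel_metrics(mask, config$pixel_per_um)
      stage <- "trafficking"
      counts <- count_trafficking(v, thr, radius_px = config$trafficking$radius_px,
                                  quality_scale = config$trafficking$quality_scale,
                                  max_link_px = config$trafficking$max_link_px,
                                  window_s = config$trafficking$window_s)
      data.frame(
        source_id = if (nzchar(v$source_id)) v$source_id else sprintf("video_%d", i),
        n_vessels = met$n_vessels,
        vessel_area_fraction = met$area_fraction,
        mean_vessel_diameter_um = if (met$n_vessels > 0)
          mean(met$diameters_um$mean_diameter_um) else NA_real_,
        max_vessel_diameter_um = if (met$n_vessels > 0)
          max(met$diameters_um$max_diameter_um) else NA_real_,
        trafficking_0.6s = unname(counts[1]),
        trafficking_0.8s = unname(counts[2]),
        trafficking_1.0s = unname(counts[3]),
        residual_motion = residual)
    }, error = function(e)
      stop("pipeline stage '", stage, "' failed for video ", i, ": ",
           conditionMessage(e)))
    res
  })
  quant <- do.call(rbind, rows)

  result <- list(quantification = quant)
  if (!is.null(feature_table)) {
    if (is.character(feature_table)) feature_table <- read_feature_table(feature_table)
    if (config$phenotyping$enabled) {
      model <- fit_phenotype_model(feature_table,
                                   n_clusters = config$phenotyping$n_clusters,
                                   variance_retained = config$phenotyping$variance_retained)
      model <- tryCatch(assign_phenotype_labels(model), error = function(e) model)
      result$phenotype_model <- model
    }
    if (config$response$enabled && !is.null(feature_table$response)) {
      result$response_models <- forward_select(
        feature_table, feature_table$feature_names,
        mode = config$response$mode,
        max_features = config$response$max_features,
        cutoff = config$response$cutoff)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(quant, file.path(out_dir, "quantification.csv"),
                     row.names = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.json"))
  }
  result
}
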
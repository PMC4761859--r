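#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the pipeline in one structured object so that
#' all thresholds are configuration, not constants, and are echoed into
#' every output for provenance.
#'
#' @param segmentation A [segmentation_params()].
#' @param dialect An [imu_dialect()] for reading trial files.
#' @param unit_threshold Movement-unit threshold (deg/s on the rotational
#'   channel).
#' @param speed_channel `"rotational"` or `"translational"`.
#' @param mirror A [mirror_model()] or `NULL` when no frames are processed.
#' @param reference_skin_ab Skin chroma reference for cluster selection.
#' @param kmeans_restarts Restarts of the K-means initialization.
#' @param pano_w,pano_h Panorama size in pixels.
#' @param seed Seed used for every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(segmentation = segmentation_params(),
                       dialect = imu_dialect(),
                       unit_threshold = 8,
                       speed_channel = "rotational",
                       mirror = NULL,
                       reference_skin_ab = c(14, 17),
                       kmeans_restarts = 10,
                       pano_w = 280, pano_h = 140,
                       seed = 1) {
  structure(list(segmentation = segmentation, dialect = dialect,
                 unit_threshold = unit_threshold,
                 speed_channel = speed_channel, mirror = mirror,
                 reference_skin_ab = reference_skin_ab,
                 kmeans_restarts = kmeans_restarts,
                 pano_w = pano_w, pano_h = pano_h, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Sections mirror the [run_config()] arguments; absent keys keep their
#' defaults. The `mirror` section takes `center_px`, `r_inner_px`,
#' `r_outer_px` and the metric cylinder constants.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_format(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  dia <- do.call(imu_dialect, y$dialect %||% list())
  mir <- if (!is.null(y$mirror)) do.call(mirror_model, y$mirror) else NULL
  run_config(segmentation = seg, dialect = dia,
             unit_threshold = y$unit_threshold %||% 8,
             speed_channel = y$speed_channel %||% "rotational",
             mirror = mir,
             reference_skin_ab = unlist(y$reference_skin_ab %||% c(14, 17)),
             kmeans_restarts = y$kmeans_restarts %||% 10,
             pano_w = y$pano_w %||% 280, pano_h = y$pano_h %||% 140,
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic provenance hash of the configuration
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_rec(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}
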
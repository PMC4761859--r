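# broom-style accessors for the fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trial segmentation into an event table
#'
#' @param x A `grasp_segmentation`.
#' @param ... Ignored.
#' @return Tibble with one row per detected event: `event`, `t`.
#' @method tidy grasp_segmentation
#' @export
tidy.grasp_segmentation <- function(x, ...) {
  ev <- x$events
  out <- tibble::tibble(
    event = c("A", "B", "C", "D", "E"),
    label = c("contact", "onset", "apex", "table_contact", "orientation_return"),
    t = c(ev$tA, ev$tB, ev$tC, ev$tD, ev$tE))
  out[!is.na(out$t), ]
}

#' One-row summary of a trial segmentation
#'
#' @param x A `grasp_segmentation`.
#' @param ... Ignored.
#' @return One-row tibble: phase durations and percentages, the closing
#'   criterion, and the thresholds used.
#' @method glance grasp_segmentation
#' @export
glance.grasp_segmentation <- function(x, ...) {
  dplyr::bind_cols(
    x$phases,
    tibble::tibble(criterion_end = x$events$criterion_end,
                   baseline_deg = x$baseline,
                   contact_threshold = x$params$contact_threshold,
                   onset_angle_delta = x$params$onset_angle_delta))
}

#' Tidy a skin segmentation into a centroid table
#'
#' @param x A `skin_segmentation`.
#' @param ... Ignored.
#' @return Tibble with one row per cluster: CIELAB centroid, pixel count,
#'   whether it is the skin cluster.
#' @method tidy skin_segmentation
#' @export
tidy.skin_segmentation <- function(x, ...) {
  k <- nrow(x$centroids)
  counts <- tabulate(x$labels[!is.na(x$labels)], nbins = k)
  tibble::tibble(cluster = seq_len(k),
                 L = x$centroids[, 1], a = x$centroids[, 2], b = x$centroids[, 3],
                 n_px = counts, skin = seq_len(k) == x$skin_cluster)
}

#' One-row summary of a skin segmentation
#'
#' @param x A `skin_segmentation`.
#' @param ... Ignored.
#' @return One-row tibble: grasp area, skin pixel count and fraction, seed.
#' @method glance skin_segmentation
#' @export
glance.skin_segmentation <- function(x, ...) {
  valid <- sum(!is.na(x$mask))
  tibble::tibble(grasp_area_mm2 = x$grasp_area_mm2,
                 n_skin_px = sum(x$mask, na.rm = TRUE),
                 skin_fraction = sum(x$mask, na.rm = TRUE) / valid,
                 seed = x$seed)
}
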
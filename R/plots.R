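# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

event_marks <- function(events) {
  ev <- tibble::tibble(
    event = c("A", "B", "C", "D", "E"),
    t = c(events$tA, events$tB, events$tC, events$tD, events$tE))
  ev[!is.na(ev$t), ]
}

#' Plot a segmented trial
#'
#' Resultant gravity-compensated acceleration and sagittal Euler angle over
#' time, annotated with the detected key instants A-E.
#'
#' @param object A `grasp_segmentation`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot grasp_segmentation
#' @export
autoplot.grasp_segmentation <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(t = object$lin$t, value = object$lin$resultant,
                   channel = "resultant linear acceleration (m/s²)"),
    tibble::tibble(t = object$filtered$t, value = object$filtered$eulerY,
                   channel = "Euler angle Y (deg)"))
  ev <- event_marks(object$events)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(data = ev, ggplot2::aes(xintercept = .data$t),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_text(data = ev, ggplot2::aes(x = .data$t, label = .data$event),
                       y = Inf, vjust = 1.3, size = 3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Drinking-simulation trial: key instants A–E")
}

#' Plot a metric panorama
#'
#' @param object A `panoramic_image`.
#' @param ... Ignored.
#' @return A ggplot object with mm axes.
#' @method autoplot panoramic_image
#' @export
autoplot.panoramic_image <- function(object, ...) {
  px <- object$pixels
  d <- dim(px)
  xs <- (seq_len(d[2]) - 0.5) * object$mm_per_px_x
  ys <- object$height_mm - (seq_len(d[1]) - 0.5) * object$mm_per_px_y
  if (length(d) == 3) {
    px[is.na(px)] <- 0
    fill <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  } else {
    g <- px; g[is.na(g)] <- 0
    fill <- grDevices::gray(pmin(pmax(g, 0), 1))
  }
  dat <- tibble::tibble(x = rep(xs, each = d[1]), y = rep(ys, d[2]),
                        fill = as.vector(fill))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "circumference (mm)", y = "height (mm)")
}

#' Plot a skin segmentation mask
#'
#' @param object A `skin_segmentation`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot skin_segmentation
#' @export
autoplot.skin_segmentation <- function(object, ...) {
  m <- object$mask
  d <- dim(m)
  dat <- tibble::tibble(x = rep(seq_len(d[2]), each = d[1]),
                        y = rep(rev(seq_len(d[1])), d[2]),
                        skin = as.vector(m))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, fill = .data$skin)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("TRUE" = "#c98b6b", "FALSE" = "grey90"),
                               na.value = "white", name = "skin") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "px (azimuth)", y = "px (height)",
                  title = sprintf("grasp area %.0f mm²", object$grasp_area_mm2))
}

#' Plot a speed profile with its movement units
#'
#' @param speed Tibble with `t` and `speed` (e.g. from [rotation_speed()]).
#' @param threshold Movement-unit threshold drawn as a reference.
#' @return A ggplot object.
#' @export
plot_speed_profile <- function(speed, threshold = 8) {
  ggplot2::ggplot(speed, ggplot2::aes(.data$t, .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "rotation speed (deg/s)")
}
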
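# Catadioptric geometry. Images are arrays as read by png::readPNG:
# [row, col] or [row, col, channel], values in [0, 1], row 1 at the top.
# Pixel coordinates: x = column, y = row; azimuth theta is measured from the
# camera's +x axis, counterclockwise in the scene (i.e. with y flipped).

#' Mirror/cylinder calibration model
#'
#' Maps pixels of the annular mirror image to the grasped cylinder surface.
#' The visible surface unrolls to circumference x usable length; the device
#' images a 140 mm circumference over a 100 mm cylinder of which the bottom
#' 30 mm band is rejected (the mirror concentrates it into a few
#' low-resolution pixels), leaving a 140 x 70 mm metric panorama.
#'
#' @param center_px Principal point `c(x, y)` of the annulus, pixels.
#' @param r_inner_px,r_outer_px Valid annulus radii, pixels.
#' @param radius_to_height Optional two-column data frame
#'   (`radius_px`, `height_mm`), strictly monotone, giving the calibrated
#'   mapping from image radius to cylinder height. Default: linear between
#'   (`r_inner_px`, cylinder top) and (`r_outer_px`, rejected-band
#'   boundary). A measured table from the true single-viewpoint mirror
#'   profile can be supplied instead.
#' @param cylinder_circumference_mm Default 140.
#' @param cylinder_length_mm Default 100.
#' @param reject_bottom_mm Bottom band excluded from the panorama, default 30.
#' @return A list of class `mirror_model`.
#' @export
mirror_model <- function(center_px, r_inner_px, r_outer_px,
                         radius_to_height = NULL,
                         cylinder_circumference_mm = 140,
                         cylinder_length_mm = 100,
                         reject_bottom_mm = 30) {
  if (!(r_inner_px > 0 && r_inner_px < r_outer_px)) {
    abort_parameter("need 0 < r_inner_px < r_outer_px")
  }
  if (!(reject_bottom_mm >= 0 && reject_bottom_mm < cylinder_length_mm)) {
    abort_parameter("need 0 <= reject_bottom_mm < cylinder_length_mm")
  }
  if (is.null(radius_to_height)) {
    radius_to_height <- data.frame(
      radius_px = c(r_inner_px, r_outer_px),
      height_mm = c(cylinder_length_mm, reject_bottom_mm))
  }
  r2h <- radius_to_height
  if (is.unsorted(r2h$radius_px, strictly = TRUE)) {
    abort_parameter("radius_to_height$radius_px must be strictly increasing")
  }
  dh <- diff(r2h$height_mm)
  if (!(all(dh > 0) || all(dh < 0))) {
    abort_parameter("radius_to_height must be strictly monotone in height")
  }
  structure(list(center_px = center_px,
                 r_inner_px = r_inner_px, r_outer_px = r_outer_px,
                 radius_to_height = r2h,
                 cylinder_circumference_mm = cylinder_circumference_mm,
                 cylinder_length_mm = cylinder_length_mm,
                 reject_bottom_mm = reject_bottom_mm),
            class = "mirror_model")
}

height_for_radius <- function(model, r) {
  stats::approx(model$radius_to_height$radius_px,
                model$radius_to_height$height_mm, xout = r, rule = 1)$y
}

radius_for_height <- function(model, h) {
  r2h <- model$radius_to_height
  o <- order(r2h$height_mm)
  stats::approx(r2h$height_mm[o], r2h$radius_px[o], xout = h, rule = 1)$y
}

img_gray <- function(img) {
  if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
}

#' Locate the mirror annulus in an omnidirectional frame
#'
#' Estimates the principal point as the intensity centroid of the bright
#' mirror region and the annulus radii from the radial extent of that
#' region. Intended for clean calibration frames; results are normally
#' reviewed and can be overridden in the mirror model.
#'
#' @param omni Image array (grayscale or RGB, values in \[0, 1\]).
#' @param contrast_floor Minimum image contrast below which no annulus is
#'   declared (default 0.1).
#' @return List with `center_px = c(x, y)`, `r_inner_px`, `r_outer_px`.
#' @export
detect_annulus <- function(omni, contrast_floor = 0.1) {
  g <- img_gray(omni)
  rng <- range(g)
  if (diff(rng) < contrast_floor) {
    abort_calibration("no annulus found: image contrast below floor")
  }
  thr <- mean(rng)
  bright <- which(g > thr, arr.ind = TRUE)
  cx <- mean(bright[, 2]); cy <- mean(bright[, 1])
  r <- sqrt((bright[, 2] - cx)^2 + (bright[, 1] - cy)^2)
  q <- stats::quantile(r, c(0.001, 0.999), names = FALSE)
  list(center_px = c(cx, cy), r_inner_px = q[1], r_outer_px = q[2])
}

# bilinear sampling of one channel at fractional (x=col, y=row)
bilinear_sample <- function(ch, x, y) {
  nr <- nrow(ch); nc <- ncol(ch)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nc & y0 + 1 <= nr & !is.na(x0) & !is.na(y0)
  out <- rep(NA_real_, length(x))
  i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
  i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
  out[ok] <- ch[i00] * (1 - fx[ok]) * (1 - fy[ok]) + ch[i01] * fx[ok] * (1 - fy[ok]) +
    ch[i10] * (1 - fx[ok]) * fy[ok] + ch[i11] * fx[ok] * fy[ok]
  out
}

#' Unwrap an omnidirectional frame into a metric panorama
#'
#' Each output pixel (row, col) corresponds to azimuth
#' theta = 360 * (col - 0.5) / out_w degrees and cylinder height running
#' from the cylinder top (row 1) down to the rejected-band boundary (last
#' row); the source radius is the inverse of the model's radius-to-height
#' calibration, sampled with bilinear interpolation. Column 1 and the last
#' column are adjacent on the cylinder (full 360 degree wrap). Pixels whose
#' source radius falls outside the valid annulus are `NA`, never
#' extrapolated.
#'
#' @param omni Image array (grayscale matrix or RGB array, values \[0, 1\]).
#' @param model A [mirror_model()].
#' @param out_w,out_h Output size in pixels (both >= 8). Default 280 x 140,
#'   i.e. 0.5 mm/px on the device geometry.
#' @return An object of class `panoramic_image`: list with `pixels`,
#'   `width_mm`, `height_mm`, `mm_per_px_x`, `mm_per_px_y`,
#'   `azimuth_origin_deg` (0 = camera +x axis).
#' @export
unwrap <- function(omni, model, out_w = 280, out_h = 140) {
  if (out_w < 8 || out_h < 8) abort_parameter("out_w and out_h must be >= 8")
  L <- model$cylinder_length_mm
  B <- model$reject_bottom_mm
  theta <- 2 * pi * (seq_len(out_w) - 0.5) / out_w
  h <- L - (L - B) * (seq_len(out_h) - 0.5) / out_h
  r <- radius_for_height(model, h)
  r[!is.na(r) & (r < model$r_inner_px - 1e-9 | r > model$r_outer_px + 1e-9)] <- NA
  # out grid: rows = heights, cols = azimuths
  xs <- model$center_px[1] + outer(r, cos(theta))
  ys <- model$center_px[2] - outer(r, sin(theta))
  sample_all <- function(ch) {
    matrix(bilinear_sample(ch, as.vector(xs), as.vector(ys)), nrow = out_h)
  }
  px <- if (length(dim(omni)) == 3) {
    out <- array(NA_real_, c(out_h, out_w, dim(omni)[3]))
    for (k in seq_len(dim(omni)[3])) out[, , k] <- sample_all(omni[, , k])
    out
  } else {
    sample_all(omni)
  }
  structure(list(pixels = px,
                 width_mm = model$cylinder_circumference_mm,
                 height_mm = L - B,
                 mm_per_px_x = model$cylinder_circumference_mm / out_w,
                 mm_per_px_y = (L - B) / out_h,
                 azimuth_origin_deg = 0),
            class = "panoramic_image")
}

#' @export
print.panoramic_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<panoramic_image> %d x %d px, %.0f x %.0f mm (%.2f x %.2f mm/px)\n",
              d[2], d[1], x$width_mm, x$height_mm, x$mm_per_px_x, x$mm_per_px_y))
  invisible(x)
}
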
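# Synthetic omnidirectional frames: skin-colored finger bands painted on
# the cylinder surface in (azimuth, height) space, forward-projected onto
# the mirror annulus, composited over glass and background colors, with
# Gaussian chroma noise in CIELAB.

#' Default finger-band layout for synthetic frames
#'
#' Four 15-degree-wide bands (index to little finger) spanning most of the
#' usable cylinder height, in degrees and mm on the cylinder surface.
#'
#' @param n_bands Number of finger bands.
#' @param width_deg Angular width of each band.
#' @param spacing_deg Center-to-center spacing.
#' @param start_deg Center of the first band.
#' @param h_min,h_max Height extent on the cylinder, mm.
#' @return Tibble with `theta_min`, `theta_max`, `h_min`, `h_max`.
#' @export
hand_spec <- function(n_bands = 4, width_deg = 15, spacing_deg = 30,
                      start_deg = 60, h_min = 40, h_max = 95) {
  centers <- start_deg + spacing_deg * (seq_len(n_bands) - 1)
  tibble::tibble(theta_min = centers - width_deg / 2,
                 theta_max = centers + width_deg / 2,
                 h_min = h_min, h_max = h_max)
}

#' Default scene colors in CIELAB
#'
#' Mid-tone skin, pale low-chroma glass, dark blue background.
#'
#' @return Named list of length-3 Lab vectors.
#' @export
frame_colors <- function() {
  list(skin = c(65, 14, 17), glass = c(78, 0, 2), background = c(20, -5, -25))
}

band_membership <- function(theta_deg, h_mm, bands) {
  inside <- rep(FALSE, length(theta_deg))
  for (i in seq_len(nrow(bands))) {
    inside <- inside |
      (theta_deg >= bands$theta_min[i] & theta_deg <= bands$theta_max[i] &
         h_mm >= bands$h_min[i] & h_mm <= bands$h_max[i])
  }
  inside
}

#' Render a synthetic omnidirectional frame with ground truth
#'
#' @param model A [mirror_model()] (supplies the annulus geometry and the
#'   radius-to-height mapping that the forward projection inverts).
#' @param bands A [hand_spec()] layout; bands must lie within
#'   \[0, 360) degrees and \[0, cylinder length\] mm.
#' @param colors CIELAB scene colors, see [frame_colors()].
#' @param noise_sd Gaussian chroma noise SD applied to a* and b* inside the
#'   annulus (default 3).
#' @param seed Integer seed.
#' @param width_px,height_px Frame size; default fits the annulus with an
#'   8 px margin.
#' @param table_band_h_mm Heights below this show the background color
#'   through the transparent glass (the table surface seen past the
#'   cylinder bottom; default 38 mm), so frames carry the three color
#'   populations — skin, glass, background — that the clustering expects.
#' @param truth_w,truth_h Size of the ground-truth panoramic mask
#'   (default 280 x 140, matching [unwrap()] defaults).
#' @return List with `image` (H x W x 3 sRGB array), `truth` (list:
#'   `skin_mask` in panoramic coordinates at pixel centers, `bands`,
#'   `painted_area_mm2` of the visible band surface, `colors`, `seed`).
#' @export
synth_omni_frame <- function(model, bands = hand_spec(),
                             colors = frame_colors(), noise_sd = 3, seed = 1,
                             width_px = NULL, height_px = NULL,
                             table_band_h_mm = 38,
                             truth_w = 280, truth_h = 140) {
  if (any(bands$theta_min < 0 | bands$theta_max >= 360 |
            bands$h_min < 0 | bands$h_max > model$cylinder_length_mm)) {
    abort_parameter("hand bands must lie within [0, 360) degrees x [0, cylinder length] mm")
  }
  cx <- model$center_px[1]; cy <- model$center_px[2]
  if (is.null(width_px)) width_px <- ceiling(2 * (model$r_outer_px + 8))
  if (is.null(height_px)) height_px <- ceiling(2 * (model$r_outer_px + 8))

  col_i <- matrix(rep(seq_len(width_px), each = height_px), height_px)
  row_i <- matrix(rep(seq_len(height_px), width_px), height_px)
  dx <- col_i - cx
  dy <- cy - row_i
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  in_annulus <- r >= model$r_inner_px & r <= model$r_outer_px
  h <- height_for_radius(model, pmin(pmax(r, model$r_inner_px), model$r_outer_px))

  skin_px <- in_annulus & band_membership(theta, h, bands)
  table_px <- in_annulus & !skin_px & h < table_band_h_mm
  lab_px <- matrix(rep(unlist(colors$background), each = length(r)), ncol = 3)
  lab_px[in_annulus, ] <- matrix(rep(colors$glass, each = sum(in_annulus)), ncol = 3)
  lab_px[table_px, ] <- matrix(rep(colors$background, each = sum(table_px)), ncol = 3)
  lab_px[skin_px, ] <- matrix(rep(colors$skin, each = sum(skin_px)), ncol = 3)
  lab_px[in_annulus, 2:3] <- lab_px[in_annulus, 2:3] +
    withr::with_seed(seed, matrix(stats::rnorm(2 * sum(in_annulus), 0, noise_sd), ncol = 2))

  # convert annulus pixels per-pixel, background as a single color
  rgb_px <- matrix(rep(grDevices::convertColor(matrix(unlist(colors$background), 1),
                                               from = "Lab", to = "sRGB", clip = TRUE),
                       each = length(r)), ncol = 3)
  rgb_px[in_annulus, ] <- grDevices::convertColor(lab_px[in_annulus, , drop = FALSE],
                                                  from = "Lab", to = "sRGB", clip = TRUE)
  img <- array(as.vector(rgb_px), c(height_px, width_px, 3))

  # analytic ground-truth skin mask at panoramic pixel centers
  L <- model$cylinder_length_mm; B <- model$reject_bottom_mm
  th_c <- 360 * (seq_len(truth_w) - 0.5) / truth_w
  h_c <- L - (L - B) * (seq_len(truth_h) - 0.5) / truth_h
  grid_theta <- matrix(rep(th_c, each = truth_h), truth_h)
  grid_h <- matrix(rep(h_c, truth_w), truth_h)
  mask <- matrix(band_membership(as.vector(grid_theta), as.vector(grid_h), bands),
                 truth_h, truth_w)

  visible <- pmin(bands$h_max, L) - pmax(bands$h_min, B)
  area <- sum(pmax(visible, 0) * (bands$theta_max - bands$theta_min) / 360 *
                model$cylinder_circumference_mm)

  list(image = img,
       truth = list(skin_mask = mask, bands = bands,
                    painted_area_mm2 = area, colors = colors, seed = seed))
}

#' Forward-render an intensity pattern defined on the cylinder surface
#'
#' Paints `pattern_fn(theta_deg, h_mm)` onto the mirror annulus through the
#' model's radius-to-height mapping (the inverse of [unwrap()]), producing a
#' grayscale omni frame. Used to validate the unwrap geometry: a pattern
#' rendered forward and unwrapped must come back at its (theta, h)
#' position.
#'
#' @param model A [mirror_model()].
#' @param pattern_fn Vectorized function of (theta_deg in \[0, 360),
#'   h_mm) returning intensity in \[0, 1\].
#' @param width_px,height_px Frame size; default fits the annulus.
#' @return Grayscale image matrix; 0 outside the annulus.
#' @export
render_pattern <- function(model, pattern_fn,
                           width_px = NULL, height_px = NULL) {
  cx <- model$center_px[1]; cy <- model$center_px[2]
  if (is.null(width_px)) width_px <- ceiling(2 * (model$r_outer_px + 8))
  if (is.null(height_px)) height_px <- ceiling(2 * (model$r_outer_px + 8))
  col_i <- matrix(rep(seq_len(width_px), each = height_px), height_px)
  row_i <- matrix(rep(seq_len(height_px), width_px), height_px)
  dx <- col_i - cx
  dy <- cy - row_i
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  in_annulus <- r >= model$r_inner_px & r <= model$r_outer_px
  h <- height_for_radius(model, pmin(pmax(r, model$r_inner_px), model$r_outer_px))
  img <- matrix(0, height_px, width_px)
  img[in_annulus] <- pattern_fn(theta[in_annulus], h[in_annulus])
  img
}
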
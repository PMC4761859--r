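# Skin segmentation in CIELAB. Clustering runs on (a*, b*) chroma by
# default: lightness carries the sheen/shading variation of the glass and
# hand while chroma separates skin from glass and background.

#' Convert an sRGB image to CIELAB
#'
#' Standard sRGB to CIELAB under D65; L in \[0, 100\]. `NA` pixels (e.g.
#' outside the valid annulus after unwrapping) stay `NA`.
#'
#' @param rgb H x W x 3 array with values in \[0, 1\].
#' @return H x W x 3 array of L*, a*, b*.
#' @export
to_lab <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3) {
    abort_format("to_lab expects an H x W x 3 sRGB array")
  }
  flat <- matrix(as.vector(rgb), ncol = 3)
  ok <- stats::complete.cases(flat)
  lab <- matrix(NA_real_, nrow(flat), 3)
  if (any(ok)) {
    lab[ok, ] <- grDevices::convertColor(flat[ok, , drop = FALSE],
                                         from = "sRGB", to = "Lab")
  }
  array(as.vector(lab), d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  flat <- matrix(as.vector(lab), ncol = 3)
  rgb <- grDevices::convertColor(flat, from = "Lab", to = "sRGB", clip = TRUE)
  array(as.vector(rgb), d)
}

#' K-means color clustering of a CIELAB image
#'
#' Lloyd's algorithm with Euclidean distance on the chroma coordinates
#' (a*, b*) by default, or on all three CIELAB channels. Three clusters
#' separate hand skin, glass/cylinder and background in the device's
#' frames. Initialization is seeded and restarted; the best of `restarts`
#' runs (lowest within-cluster sum of squares) is kept.
#'
#' @param lab H x W x 3 CIELAB array (from [to_lab()]).
#' @param k Number of clusters (default 3).
#' @param seed Integer RNG seed for reproducible initialization.
#' @param restarts Number of seeded restarts (default 10).
#' @param channels `"chroma"` for (a*, b*) (default) or `"lab"` for all
#'   three channels.
#' @return List with `labels` (H x W integer matrix in 1..k, `NA` for
#'   invalid pixels) and `centroids` (k x 3 matrix of L*, a*, b*; L* is the
#'   cluster mean even when clustering on chroma only).
#' @export
kmeans_lab <- function(lab, k = 3, seed = 1, restarts = 10,
                       channels = c("chroma", "lab")) {
  channels <- match.arg(channels)
  d <- dim(lab)
  flat <- matrix(as.vector(lab), ncol = 3)
  ok <- stats::complete.cases(flat)
  feat <- if (channels == "chroma") flat[ok, 2:3, drop = FALSE] else flat[ok, , drop = FALSE]
  if (nrow(unique(feat)) < k) {
    abort_degenerate(sprintf("fewer than %d distinct colors present", k))
  }
  # Lloyd can cycle indefinitely between equivalent assignments of points
  # equidistant to two centroids; the assignment at iter.max is as good as
  # any of them, so the convergence warning is not informative here
  km <- withr::with_seed(seed, suppressWarnings(
    stats::kmeans(feat, centers = k, nstart = restarts,
                  iter.max = 200, algorithm = "Lloyd")))
  labels <- matrix(NA_integer_, d[1], d[2])
  labels[ok] <- km$cluster
  centroids <- matrix(NA_real_, k, 3,
                      dimnames = list(NULL, c("L", "a", "b")))
  for (j in seq_len(k)) {
    centroids[j, ] <- colMeans(flat[ok, , drop = FALSE][km$cluster == j, , drop = FALSE])
  }
  list(labels = labels, centroids = centroids)
}

#' Select the skin cluster
#'
#' The cluster whose chroma centroid lies nearest (Euclidean in a*b*) to a
#' reference skin chroma. The default (a* = 14, b* = 17) is a mid-tone skin
#' locus; skin tones vary, so per-cohort calibration from one labeled frame
#' is recommended and the reference is always a configuration value.
#'
#' @param centroids k x 3 centroid matrix (L*, a*, b*) from [kmeans_lab()].
#' @param reference_skin_ab Chroma reference `c(a, b)`.
#' @return Index of the skin cluster.
#' @export
select_skin_cluster <- function(centroids, reference_skin_ab = c(14, 17)) {
  dist2 <- (centroids[, 2] - reference_skin_ab[1])^2 +
    (centroids[, 3] - reference_skin_ab[2])^2
  o <- order(dist2)
  if (length(dist2) > 1 && abs(sqrt(dist2[o[1]]) - sqrt(dist2[o[2]])) < 1e-6) {
    abort_ambiguous("two centroids are equidistant from the skin reference; select manually")
  }
  o[1]
}

# binary mask with connected components smaller than min_px removed
filter_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask, na.rm = TRUE)) return(mask)
  m <- mask
  m[is.na(m)] <- FALSE
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out[is.na(mask)] <- NA
  out
}

#' Grasp contact area from a skin mask
#'
#' Pixel count of the skin mask times the metric pixel area, after removing
#' connected components below a minimum size (speckle from chroma noise).
#'
#' @param seg A `skin_segmentation` (or a logical mask matrix).
#' @param pano The [unwrap()] panorama the mask is aligned to (supplies
#'   mm-per-pixel calibration).
#' @param min_component_px Minimum connected-component size kept
#'   (default 25).
#' @return Area in mm².
#' @export
grasp_area <- function(seg, pano, min_component_px = 25) {
  mask <- if (is.matrix(seg)) seg else seg$mask
  mask <- filter_small_components(mask, min_component_px)
  sum(mask, na.rm = TRUE) * pano$mm_per_px_x * pano$mm_per_px_y
}

#' Segment skin in a panorama and quantify grasp area
#'
#' Full color pipeline on an unwrapped panorama: CIELAB conversion, 3-way
#' K-means on chroma, skin-cluster selection against the reference chroma,
#' small-component removal, and metric grasp area.
#'
#' @param pano A `panoramic_image` with RGB pixels.
#' @param k,seed,restarts,channels Passed to [kmeans_lab()].
#' @param reference_skin_ab Passed to [select_skin_cluster()].
#' @param max_skin_ab_distance No cluster counts as skin if its chroma
#'   centroid lies farther than this from the reference (default 12 a*b*
#'   units): a frame without a hand then yields an empty mask instead of
#'   promoting glass or background to skin. Centroid noise at the device's
#'   chroma noise level is well under 1 unit, while glass and background
#'   sit 20+ units from the skin locus.
#' @param min_component_px Passed to [grasp_area()].
#' @return Object of class `skin_segmentation`: list with `labels`,
#'   `centroids`, `skin_cluster`, `mask` (component-filtered), and
#'   `grasp_area_mm2`.
#' @examples
#' mdl <- mirror_model(c(320, 320), 100, 300)
#' fr <- synth_omni_frame(mdl, seed = 1, width_px = 640, height_px = 640)
#' seg <- segment_skin(unwrap(fr$image, mdl), seed = 1)
#' seg$grasp_area_mm2
#' @export
segment_skin <- function(pano, k = 3, seed = 1, restarts = 10,
                         channels = "chroma",
                         reference_skin_ab = c(14, 17),
                         max_skin_ab_distance = 12,
                         min_component_px = 25) {
  lab <- to_lab(pano$pixels)
  km <- kmeans_lab(lab, k = k, seed = seed, restarts = restarts,
                   channels = channels)
  skin <- select_skin_cluster(km$centroids, reference_skin_ab)
  dist_ab <- sqrt((km$centroids[skin, 2] - reference_skin_ab[1])^2 +
                    (km$centroids[skin, 3] - reference_skin_ab[2])^2)
  if (dist_ab > max_skin_ab_distance) {
    skin <- NA_integer_
  }
  mask <- !is.na(km$labels) & !is.na(skin) & km$labels %in% skin
  mask_f <- filter_small_components(mask, min_component_px)
  structure(list(labels = km$labels, centroids = km$centroids,
                 skin_cluster = skin, mask = mask_f,
                 grasp_area_mm2 = sum(mask_f, na.rm = TRUE) *
                   pano$mm_per_px_x * pano$mm_per_px_y,
                 seed = seed, channels = channels,
                 reference_skin_ab = reference_skin_ab),
            class = "skin_segmentation")
}

#' @export
print.skin_segmentation <- function(x, ...) {
  cat(sprintf("<skin_segmentation> skin cluster %d of %d, area %.1f mm^2\n",
              x$skin_cluster, nrow(x$centroids), x$grasp_area_mm2))
  invisible(x)
}

#' Grasp posture at the task key instants
#'
#' For each detected event (A-E), picks the omni frame nearest in time,
#' unwraps it and segments skin. Events whose nearest frame is farther than
#' two frame periods away are skipped with a warning.
#'
#' @param frames Tibble with columns `t` (seconds) and `image` (list of
#'   image arrays), or `path` (PNG file paths read on demand).
#' @param events A [task_events()] row.
#' @param model A [mirror_model()].
#' @param ... Passed to [segment_skin()].
#' @param out_w,out_h Panorama size, passed to [unwrap()].
#' @return Tibble with one row per event kept: `event`, `t_event`,
#'   `t_frame`, `pano` (list), `seg` (list), `grasp_area_mm2`.
#' @export
posture_at_events <- function(frames, events, model, out_w = 280, out_h = 140, ...) {
  ev <- tibble::tibble(
    event = c("A", "B", "C", "D", "E"),
    t_event = c(events$tA, events$tB, events$tC, events$tD, events$tE))
  ev <- ev[!is.na(ev$t_event), ]
  period <- stats::median(diff(sort(frames$t)))
  rows <- purrr::pmap(ev, function(event, t_event) {
    i <- which.min(abs(frames$t - t_event))
    if (abs(frames$t[i] - t_event) > 2 * period) {
      rlang::warn(sprintf("event %s at %.3f s: nearest frame is %.3f s away; skipped",
                          event, t_event, abs(frames$t[i] - t_event)))
      return(NULL)
    }
    img <- if ("image" %in% names(frames)) frames$image[[i]] else png::readPNG(frames$path[i])
    pano <- unwrap(img, model, out_w = out_w, out_h = out_h)
    sseg <- segment_skin(pano, ...)
    area <- sseg$grasp_area_mm2
    tibble::tibble(event = event, t_event = t_event, t_frame = frames$t[i],
                   pano = list(pano), seg = list(sseg),
                   grasp_area_mm2 = area)
  })
  dplyr::bind_rows(rows)
}
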
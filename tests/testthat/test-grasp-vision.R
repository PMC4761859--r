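# Mirror geometry, panoramic unwrapping and CIELAB skin segmentation.

mdl_small <- mirror_model(c(160, 160), 50, 150)

test_that("mirror model validates geometry and monotone calibration", {
  expect_graspkin_error(mirror_model(c(0, 0), 300, 100), "parameter")
  expect_graspkin_error(
    mirror_model(c(0, 0), 100, 300, reject_bottom_mm = 120), "parameter")
  expect_graspkin_error(
    mirror_model(c(0, 0), 100, 300,
                 radius_to_height = data.frame(radius_px = c(100, 200, 300),
                                               height_mm = c(100, 20, 60))),
    "parameter")
  m <- mirror_model(c(0, 0), 100, 300)
  expect_equal(graspkin:::height_for_radius(m, c(100, 300)), c(100, 30))
  expect_equal(graspkin:::radius_for_height(m, c(100, 30)), c(100, 300))
})

test_that("annulus detection recovers center and radii within 2 px", {
  mdl <- mirror_model(c(480, 640), 120, 400)  # center (x=480, y=640)
  img <- render_pattern(mdl, function(th, h) rep(1, length(th)),
                        width_px = 960, height_px = 1280)
  det <- detect_annulus(img)
  expect_lt(max(abs(det$center_px - c(480, 640))), 2)
  expect_lt(abs(det$r_inner_px - 120), 2)
  expect_lt(abs(det$r_outer_px - 400), 2)

  expect_graspkin_error(detect_annulus(matrix(0, 100, 100)), "calibration")

  # off-center annulus
  mdl2 <- mirror_model(c(300, 200), 60, 160)
  img2 <- render_pattern(mdl2, function(th, h) rep(1, length(th)),
                         width_px = 520, height_px = 420)
  det2 <- detect_annulus(img2)
  expect_lt(max(abs(det2$center_px - c(300, 200))), 2)
})

test_that("unwrap maps azimuth to columns and height to rows", {
  # radial stripe at theta = 90 deg -> vertical stripe at col out_w/4
  img <- render_pattern(mdl_small, function(th, h) as.numeric(abs(th - 90) < 4))
  pano <- unwrap(img, mdl_small, out_w = 280, out_h = 140)
  colsum <- colSums(pano$pixels, na.rm = TRUE)
  expect_equal(which.max(colsum), 70, tolerance = 2)
  expect_equal(pano$width_mm, 140)
  expect_equal(pano$height_mm, 70)

  # concentric ring at r0 -> horizontal line at its calibrated height
  r0 <- 100
  h0 <- graspkin:::height_for_radius(mdl_small, r0)
  cx <- mdl_small$center_px[1]; cy <- mdl_small$center_px[2]
  img2 <- matrix(0, 320, 320)
  rr <- sqrt((col(img2) - cx)^2 + (row(img2) - cy)^2)
  img2[abs(rr - r0) < 1.5] <- 1
  pano2 <- unwrap(img2, mdl_small, out_w = 280, out_h = 140)
  rowsum <- rowSums(pano2$pixels, na.rm = TRUE)
  exp_row <- (mdl_small$cylinder_length_mm - h0) / pano2$mm_per_px_y
  expect_equal(which.max(rowsum), exp_row, tolerance = 2)

  expect_graspkin_error(unwrap(img, mdl_small, out_w = 4), "parameter")
})

test_that("pixels outside the calibrated annulus are NA, not extrapolated", {
  # calibration table covering only the upper half of the cylinder
  m <- mirror_model(c(160, 160), 50, 150,
                    radius_to_height = data.frame(radius_px = c(50, 150),
                                                  height_mm = c(100, 65)))
  img <- render_pattern(mdl_small, function(th, h) rep(1, length(th)))
  pano <- unwrap(img, m, out_w = 64, out_h = 64)
  # heights below 65 mm resolve to radii beyond the annulus: flagged NA
  expect_true(all(is.na(pano$pixels[64, ])))
  expect_true(all(!is.na(pano$pixels[1, ])))
})

test_that("unwrap round trip localizes surface patterns within 1 px RMS", {
  mdl <- mirror_model(c(320, 320), 100, 300)
  th0 <- c(45, 160, 250, 330); h0 <- c(45, 60, 80, 90)
  img <- render_pattern(mdl, function(th, h) {
    v <- 0
    for (k in 1:4) {
      dth <- pmin(abs(th - th0[k]), 360 - abs(th - th0[k])) * 140 / 360
      v <- v + exp(-(dth^2 + (h - h0[k])^2) / (2 * 1.5^2))
    }
    pmin(v, 1)
  })
  pano <- unwrap(img, mdl, out_w = 280, out_h = 140)
  px <- pano$pixels; px[is.na(px)] <- 0
  errs <- vapply(1:4, function(k) {
    exp_col <- th0[k] / 360 * 280 + 0.5
    exp_row <- (100 - h0[k]) / 70 * 140 + 0.5
    sel <- abs(row(px) - exp_row) < 12 & abs(col(px) - exp_col) < 12
    w <- px * 0; w[sel] <- px[sel]
    sqrt((sum(col(px) * w) / sum(w) - exp_col)^2 +
           (sum(row(px) * w) / sum(w) - exp_row)^2)
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 1)
})

test_that("sRGB to CIELAB conversion hits the colorimetric anchors", {
  white <- array(1, c(1, 1, 3))
  lab <- to_lab(white)
  expect_equal(lab[1, 1, 1], 100, tolerance = 0.01)
  expect_lt(max(abs(lab[1, 1, 2:3])), 0.5)

  black <- array(0, c(1, 1, 3))
  expect_equal(to_lab(black)[1, 1, 1], 0, tolerance = 1e-6)

  gray <- array(119 / 255, c(1, 1, 3))
  expect_lt(max(abs(to_lab(gray)[1, 1, 2:3])), 0.1)

  expect_graspkin_error(to_lab(matrix(0, 4, 4)), "format")
})

test_that("K-means on chroma separates flat patches exactly, any seed", {
  # three flat color patches
  img <- array(0, c(10, 30, 3))
  img[, 1:10, ] <- rep(c(0.8, 0.5, 0.4), each = 100)   # skin-ish
  img[, 11:20, ] <- rep(c(0.5, 0.5, 0.9), each = 100)  # blue
  img[, 21:30, ] <- rep(c(0.4, 0.8, 0.4), each = 100)  # green
  lab <- to_lab(img)
  k1 <- kmeans_lab(lab, seed = 1)
  k2 <- kmeans_lab(lab, seed = 99)
  patch <- rep(1:3, each = 10)[col(k1$labels)]
  # within-patch labels constant, and the partitions agree across seeds
  expect_equal(length(unique(split(as.vector(k1$labels), patch) |>
                               vapply(function(v) v[1], integer(1)))), 3)
  expect_true(all(tapply(as.vector(k1$labels), patch,
                         function(v) length(unique(v))) == 1))
  expect_equal(unname(table(as.vector(k1$labels), as.vector(k2$labels)) > 0) |>
                 rowSums(), rep(1, 3))

  # fewer distinct colors than clusters
  flat <- array(0.5, c(5, 5, 3))
  flat[, 1:2, 1] <- 0.9
  expect_graspkin_error(kmeans_lab(to_lab(flat)), "degenerate")
})

test_that("skin cluster selection is nearest-chroma with tie detection", {
  cent <- rbind(c(65, 14, 17),   # skin locus
                c(70, 0, 0),     # neutral
                c(40, -5, -25))  # blue
  expect_identical(select_skin_cluster(cent), 1L)
  # all neutral: nearest is still returned
  cent2 <- rbind(c(65, 0, 0), c(50, 1, 1), c(40, 2, 3))
  expect_identical(select_skin_cluster(cent2), 3L)
  # exact symmetric tie
  cent3 <- rbind(c(65, 14, 16), c(65, 14, 18), c(10, 0, 0))
  expect_graspkin_error(select_skin_cluster(cent3), "ambiguous")
})

test_that("grasp area applies metric calibration and speckle removal", {
  pano <- unwrap(render_pattern(mdl_small, function(th, h) rep(1, length(th))),
                 mdl_small, out_w = 280, out_h = 140)
  empty <- matrix(FALSE, 140, 280)
  expect_equal(grasp_area(empty, pano), 0)
  full <- matrix(TRUE, 140, 280)
  expect_equal(grasp_area(full, pano), 9800)  # 140 mm x 70 mm

  # a 9-px speckle is removed, a 100-px blob kept
  m <- empty
  m[3:5, 3:5] <- TRUE
  m[50:59, 50:59] <- TRUE
  expect_equal(grasp_area(m, pano), 100 * pano$mm_per_px_x * pano$mm_per_px_y)

  # dilation monotonicity
  m2 <- m
  m2[49:60, 49:60] <- TRUE
  expect_gte(grasp_area(m2, pano), grasp_area(m, pano))
})

test_that("segmentation recovers the painted hand within tolerance", {
  mdl <- mirror_model(c(320, 320), 100, 300)
  fr <- synth_omni_frame(mdl, seed = 3)
  pano <- unwrap(fr$image, mdl)
  seg <- segment_skin(pano, seed = 3)
  expect_gte(mean(seg$mask == fr$truth$skin_mask, na.rm = TRUE), 0.99)
  expect_equal(seg$grasp_area_mm2, fr$truth$painted_area_mm2,
               tolerance = 0.03 * fr$truth$painted_area_mm2)
  td <- tidy(seg)
  expect_identical(td$cluster[td$skin], seg$skin_cluster)
  expect_equal(glance(seg)$grasp_area_mm2, seg$grasp_area_mm2)
})

test_that("posture extraction picks nearest frames and skips distant events", {
  mdl <- mirror_model(c(160, 160), 50, 150)
  frames <- tibble::tibble(
    t = seq(0.1, 3.0, by = 0.1),
    image = lapply(1:30, function(i) synth_omni_frame(mdl, seed = i,
                                                      truth_w = 64, truth_h = 64)$image))
  ev <- task_events(tA = 0.81, tB = 1.23, tC = 2.24, tD = 2.87)
  post <- posture_at_events(frames, ev, mdl, out_w = 64, out_h = 64)
  expect_equal(post$t_frame[post$event == "B"], 1.2)
  expect_setequal(post$event, c("A", "B", "C", "D"))

  ev2 <- task_events(tA = 0.81, tB = 1.23, tC = 2.24, tD = 9.5)
  expect_warning(
    post2 <- posture_at_events(frames, ev2, mdl, out_w = 64, out_h = 64),
    "skipped")
  expect_false("D" %in% post2$event)
})
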
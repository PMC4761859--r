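# Movement units, rotation speed, path reconstruction, straightness,
# activity counts and group summaries.

test_that("movement-unit counting matches the worked examples", {
  t <- seq(0, 1, length.out = 200)
  expect_identical(count_movement_units(sin(pi * t) * 300, 40), 1L)

  # maxima 300, 200, 250 with minima 120, 60: both drops qualify -> 3 units
  prof <- stats::approx(1:6, c(0, 300, 120, 200, 60, 250), n = 120)$y
  expect_identical(count_movement_units(prof, 40), 3L)

  # twin peaks with a 10 mm/s dip: one unit only
  prof2 <- stats::approx(1:4, c(0, 250, 240, 250), n = 90)$y
  expect_identical(count_movement_units(prof2, 40), 1L)

  expect_graspkin_error(count_movement_units(numeric(0), 40), "parameter")
  expect_graspkin_error(count_movement_units(c(1, 2), 0), "parameter")
  expect_graspkin_error(count_movement_units(c(1, -1), 40), "parameter")
})

test_that("hysteresis count equals the brute-force extremum-pair oracle", {
  for (sd in 1:200) {
    prof <- random_speed_profile(sd)
    thr <- withr::with_seed(sd * 7, stats::runif(1, 20, 120))
    expect_identical(count_movement_units(prof, thr),
                     oracle_movement_units(prof, thr),
                     label = sprintf("seed %d thr %.1f", sd, thr))
  }
})

test_that("raising the unit threshold never increases the count", {
  for (sd in 1:30) {
    prof <- random_speed_profile(sd)
    counts <- vapply(c(10, 20, 40, 80, 160),
                     function(th) count_movement_units(prof, th), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("rotation speed matches analytic derivatives", {
  t <- (0:499) / 87
  # linear ramp at 50 deg/s (raw derivative, no smoothing)
  sp <- rotation_speed(make_trace(t, eulerY = 50 * t), cutoff_hz = NULL)
  expect_equal(sp$speed[10:490], rep(50, 481), tolerance = 0.5)

  # sinusoid: peak speed 2*pi*f*A within 2%
  A <- 30; f <- 1
  sp <- rotation_speed(make_trace(t, eulerY = A * sin(2 * pi * f * t)))
  expect_equal(max(sp$speed), 2 * pi * f * A, tolerance = 0.02 * 2 * pi * f * A)

  sp <- rotation_speed(make_trace(t, eulerY = 12), cutoff_hz = NULL)
  expect_equal(max(sp$speed), 0)
  expect_graspkin_error(rotation_speed(make_trace((0:1) / 87)), "parameter")
})

test_that("path reconstruction inverts a minimum-jerk reach", {
  rate <- 87
  t <- (0:299) / rate
  ev <- task_events(tA = 0.2, tB = 0.5, tC = 2.5, tD = 3.0)
  # zero acceleration: the device never leaves the origin
  lin0 <- make_lin(t, rep(0, 300))
  p0 <- reconstruct_path(lin0, ev)
  expect_lt(max(abs(c(p0$x, p0$y))), 1e-9)

  # analytic 250 mm minimum-jerk reach along x over [tB, tC]
  D <- 0.25; Tt <- 2.0
  tau <- pmin(pmax((t - 0.5) / Tt, 0), 1)
  acc <- D * (60 * tau - 180 * tau^2 + 120 * tau^3) / Tt^2
  acc[t < 0.5 | t > 2.5] <- 0
  lin <- tibble::tibble(t = t, lx = acc, ly = 0, lz = 0, resultant = abs(acc))
  class(lin) <- c("lin_acc_trace", class(tibble::tibble()))
  p <- reconstruct_path(lin, ev)
  endpoint <- sqrt(p$x[nrow(p)]^2 + p$y[nrow(p)]^2)
  expect_equal(endpoint, 250, tolerance = 0.02 * 250)

  # simulator trial with a known 250 mm path, using ground-truth events
  s <- synth_trial(trial_config(seed = 61, path_length_mm = 250,
                                noise_acc_sigma = 0.002))
  lin_s <- gravity_compensate(lowpass(s$trace))
  ps <- reconstruct_path(lin_s, s$truth$events)
  end_err <- abs(sqrt(ps$x[nrow(ps)]^2 + ps$y[nrow(ps)]^2) - 250)
  expect_lt(end_err, 0.05 * 250)
})

test_that("straightness index reproduces closed forms and invariances", {
  # collinear: exactly 1
  expect_identical(straightness_index(data.frame(x = 0:10, y = 0:10 * 2)), 1)

  # 100-point semicircle: 2/pi
  th <- seq(0, pi, length.out = 100)
  semi <- data.frame(x = cos(th), y = sin(th))
  expect_equal(straightness_index(semi), 2 / pi, tolerance = 1e-3)

  # right angle, legs 300 and 400 mm: 500/700
  ell <- data.frame(x = c(0, 300, 300), y = c(0, 0, 400))
  expect_equal(straightness_index(ell), 5 / 7, tolerance = 1e-9)

  expect_graspkin_error(
    straightness_index(data.frame(x = c(1, 1), y = c(2, 2))), "metric")

  # rigid motions and scaling leave the index unchanged
  withr::with_seed(71, {
    for (i in 1:20) {
      path <- data.frame(x = cumsum(stats::rnorm(30)), y = cumsum(stats::rnorm(30)))
      s0 <- straightness_index(path)
      phi <- stats::runif(1, 0, 2 * pi); sc <- stats::runif(1, 0.1, 10)
      rot <- data.frame(
        x = sc * (cos(phi) * path$x - sin(phi) * path$y) + 5,
        y = sc * (sin(phi) * path$x + cos(phi) * path$y) - 3)
      expect_equal(straightness_index(rot), s0, tolerance = 1e-9)
    }
  })
})

test_that("activity counts integrate the resultant and add over windows", {
  t <- seq(0, 4, by = 1 / 87)
  lin <- make_lin(t, rep(1, length(t)))
  expect_equal(energy_expenditure(lin, 0, 2), 2, tolerance = 1e-6)
  expect_equal(energy_expenditure(lin, 0, 1) + energy_expenditure(lin, 1, 2),
               energy_expenditure(lin, 0, 2), tolerance = 1e-9)
  expect_equal(energy_expenditure(make_lin(t, rep(0, length(t))), 0, 2), 0)
  expect_graspkin_error(energy_expenditure(lin, 10, 11), "parameter")

  # doubling the trial's impulse amplitude increases the counts
  e <- vapply(c(0.25, 0.5, 1), function(a) {
    s <- synth_trial(trial_config(seed = 81, contact_impulse = a))
    lin <- gravity_compensate(lowpass(s$trace))
    energy_expenditure(lin, s$truth$events$tC, s$truth$events$tD)
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("group summaries give mean +/- SD in table shape", {
  m <- tibble::tibble(age = c(5, 5, 6), total_s = c(2.0, 3.0, 2.2),
                      movement_units = c(2, 3, 2))
  s <- summarize_groups(m, by = "age")
  row <- s[s$metric == "total_s" & s$group == "5", ]
  expect_equal(row$mean, 2.5)
  expect_equal(row$sd, 0.7071068, tolerance = 1e-6)
  row1 <- s[s$metric == "total_s" & s$group == "6", ]
  expect_equal(row1$sd, 0)  # single record: SD reported as 0
  expect_graspkin_error(summarize_groups(m[0, ], by = "age"), "parameter")
  expect_graspkin_error(summarize_groups(m, by = "nope"), "parameter")
})

test_that("trial metrics recover the configured movement-unit count", {
  for (nm in 1:3) {
    cfg <- if (nm == 1) {
      trial_config(seed = 90 + nm, n_movement_units = 1,
                   phase_s = c(0.45, 1.1, 1.1))
    } else {
      trial_config(seed = 90 + nm, n_movement_units = nm)
    }
    s <- synth_trial(cfg)
    m <- trial_metrics(segment_trial(s$trace))
    expect_identical(m$movement_units, nm, label = paste("n =", nm))
    expect_gte(m$movement_units, 1)
    expect_true(all(c(m$energy_transport, m$energy_return) >= 0))
  }
})
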
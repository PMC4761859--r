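# Data model, text IO, filtering and gravity compensation.

test_that("read_imu_text parses the canonical layout and validates it", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az,gx,gy,gz,eulerX,eulerY,eulerZ",
               "0.000,0,0,9.80665,0,0,0,0,0,0",
               "0.011,0,0,9.80665,0,0,0,0,0,0",
               "0.023,0,0,9.80665,0,0,0,0,0,0"), f)
  tr <- read_imu_text(f)
  expect_s3_class(tr, "imu_trace")
  expect_equal(nrow(tr), 3)
  expect_equal(imu_rate(tr), 87)

  # duplicated timestamp: validation error naming the first offending index
  writeLines(c("t,ax,ay,az,gx,gy,gz,eulerX,eulerY,eulerZ",
               "0.000,0,0,9.80665,0,0,0,0,0,0",
               "0.000,0,0,9.80665,0,0,0,0,0,0",
               "0.023,0,0,9.80665,0,0,0,0,0,0"), f)
  err <- expect_error(read_imu_text(f), class = "graspkin_error_validation")
  expect_match(conditionMessage(err), "index 1")

  # missing mandatory column is named
  writeLines(c("t,ax,ay,gx,gy,gz,eulerX,eulerY,eulerZ",
               "0.000,0,0,0,0,0,0,0,0"), f)
  err <- expect_error(read_imu_text(f), class = "graspkin_error_format")
  expect_match(conditionMessage(err), "az")
})

test_that("dialects handle delimiters, positional maps and radians", {
  f <- withr::local_tempfile(fileext = ".txt")
  # whitespace-delimited, no header, angles in radians
  writeLines(c("0.000 0 0 9.80665 0 0 0 0 0.0 0",
               "0.0115 0 0 9.80665 0 0 0 0 0.7853982 0",
               "0.023 0 0 9.80665 0 0 0 0 1.5707963 0"), f)
  dia <- imu_dialect(
    columns = c(t = 1, ax = 2, ay = 3, az = 4, gx = 5, gy = 6, gz = 7,
                eulerX = 8, eulerY = 9, eulerZ = 10),
    delim = "whitespace", angle_unit = "rad", header = FALSE)
  tr <- read_imu_text(f, dia)
  expect_equal(tr$eulerY, c(0, 45, 90), tolerance = 1e-6)
})

test_that("canonical write -> read round trip preserves every channel", {
  s <- synth_trial(trial_config(seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial(s, f)
  tr2 <- read_imu_text(f)
  for (cl in setdiff(names(s$trace), "t")) {
    expect_equal(tr2[[cl]], s$trace[[cl]], tolerance = 1e-12, label = cl)
  }
})

test_that("lowpass preserves DC, rejects out-of-band, and is zero phase", {
  rate <- 87
  t <- (0:999) / rate
  # constant specific force passes unchanged
  tr <- make_trace(t)
  out <- lowpass(tr)
  expect_equal(out$az, tr$az, tolerance = 1e-9)

  # 2 Hz kept within 2%, 40 Hz attenuated by >= 20 dB (checked in the
  # frequency domain)
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 40 * t)
  tr <- make_trace(t, ax = mix)
  y <- lowpass(tr)$ax
  sp <- Mod(stats::fft(y))[1:500] / Mod(stats::fft(mix))[1:500]
  f_axis <- (0:499) * rate / 1000
  gain_2 <- sp[which.min(abs(f_axis - 2))]
  gain_40 <- sp[which.min(abs(f_axis - 40))]
  expect_gt(gain_2, 0.98)
  expect_lt(gain_2, 1.02)
  expect_lt(20 * log10(gain_40), -20)

  # impulse response symmetric about the impulse: no group delay
  imp <- numeric(1000); imp[500] <- 1
  h <- lowpass(make_trace(t, ax = imp))$ax
  expect_equal(h[500 + 1:60], h[500 - 1:60], tolerance = 1e-9)

  # re-filtering an already deeply in-band signal is a no-op away from the
  # record boundaries (the reflection padding is exact only to first order)
  slow <- sin(2 * pi * 0.3 * t)
  y1 <- lowpass(make_trace(t, ax = slow))$ax
  y2 <- lowpass(make_trace(t, ax = y1))$ax
  interior <- 101:899
  expect_lt(max(abs(y2[interior] - y1[interior])), 1e-6)

  expect_graspkin_error(lowpass(tr, cutoff_hz = 50), "parameter")
})

test_that("gravity compensation cancels gravity at any static orientation", {
  # level device
  lin <- gravity_compensate(make_trace((0:39) / 87))
  expect_lt(max(lin$resultant), 1e-6)

  # rolled 90 degrees about X: specific force moves to the +y axis
  tr <- static_trace_at(c(90, 0, 0))
  expect_equal(tr$ay[1], graspkin:::GRAVITY_MS2, tolerance = 1e-9)
  expect_lt(max(gravity_compensate(tr)$resultant), 1e-3)

  # property: 100 random orientations, resultant < 1e-3 m/s^2
  withr::with_seed(301, {
    worst <- max(vapply(1:100, function(i) {
      max(gravity_compensate(static_trace_at(random_euler()))$resultant)
    }, numeric(1)))
  })
  expect_lt(worst, 1e-3)
})

test_that("quaternion orientation is preferred and must be normalized", {
  n <- 40; t <- (0:(n - 1)) / 87
  # quaternion says level, euler says 90 deg: quaternion wins
  tr <- imu_trace(tibble::tibble(
    t = t, ax = 0, ay = 0, az = 9.80665, gx = 0, gy = 0, gz = 0,
    eulerX = 90, eulerY = 0, eulerZ = 0,
    qw = 1, qx = 0, qy = 0, qz = 0))
  expect_lt(max(gravity_compensate(tr)$resultant), 1e-6)

  expect_graspkin_error(
    imu_trace(tibble::tibble(
      t = t, ax = 0, ay = 0, az = 9.80665, gx = 0, gy = 0, gz = 0,
      qw = 1.01, qx = 0, qy = 0, qz = 0)),
    "validation")

  # no orientation at all: capability error from the compensator
  tr <- tibble::tibble(t = t, ax = 0, ay = 0, az = 9.80665,
                       gx = 0, gy = 0, gz = 0)
  expect_graspkin_error(graspkin:::trace_rotations(tr), "capability")
})

test_that("injected contact impulses survive compensation at amplitude", {
  s <- synth_trial(trial_config(seed = 21, noise_acc_sigma = 0.002,
                                noise_angle_sigma = 0.1))
  lin <- gravity_compensate(s$trace)  # unfiltered: peak amplitude intact
  iA <- which.min(abs(lin$t - s$truth$events$tA))
  peak <- max(lin$resultant[(iA - 2):(iA + 2)])
  expect_equal(peak, 0.5, tolerance = 0.05)
})

test_that("resample_uniform regularizes jittered timestamps", {
  withr::with_seed(5, {
    t <- cumsum(stats::runif(200, 0.9, 1.1)) / 87
  })
  tr <- make_trace(t, eulerY = sin(2 * pi * 1 * t) * 30)
  out <- resample_uniform(tr)
  expect_lt(max(abs(diff(diff(out$t)))), 1e-12)
  expect_equal(out$eulerY, sin(2 * pi * out$t) * 30, tolerance = 0.01)
})
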
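# Synthetic drinking-simulation trials with exact ground truth.
#
# The sagittal angle follows quintic (minimum-jerk-style) segments: n
# velocity peaks during transport, a brief high-curvature parabolic
# turnaround at the apex (the glass meets the lip and reverses), and a
# smooth return to the initial orientation. Contact with the glass (A) and
# with the table (D) appear as raised-cosine impulses on the world-frame
# linear acceleration. The sensor-frame specific force is synthesized from
# the *reported* (noise-bearing) orientation, so the IMU's orientation and
# accelerometer outputs are mutually consistent, as a fused IMU's are.
#
# Ground-truth event times are the detector definitions evaluated on the
# noiseless profiles: tB is the analytic first crossing of the onset
# threshold (the angle ramp is shifted so that crossing lands exactly at
# tA + accommodation), tC the apex, tE the analytic return crossing, tA/tD
# the impulse centers (snapped to the sample grid).

#' Configuration of one synthetic trial
#'
#' Defaults emulate the published cohort conditions: total cycle about
#' 2.55 s split 13.3/43.1/43.5% across accommodation/transport/return,
#' 87 Hz sampling, 0.5 m/s² contact impulses of 30 ms, accelerometer noise
#' 0.005 m/s² and orientation noise 0.5 degrees.
#'
#' @param phase_s Durations `c(accommodation, transport, return)` in
#'   seconds, measured between the detector-defined events.
#' @param apex_angle_deg Peak sagittal rotation, degrees.
#' @param n_movement_units Velocity peaks in the transport phase (>= 1).
#' @param contact_impulse Impulse peak amplitude, m/s².
#' @param impulse_width_s Raised-cosine impulse width (default 0.03 s).
#' @param noise_acc_sigma Accelerometer noise SD, m/s².
#' @param noise_angle_sigma Orientation noise SD, degrees.
#' @param path_length_mm Straight-line translation of the transport reach,
#'   mm. Default 0: the study conditions model the task as rotation plus
#'   contact impulses; a nonzero value adds a minimum-jerk translation (and
#'   its acceleration defeats the second-peak table-contact rule, so use it
#'   only with ground-truth events).
#' @param onset_angle_delta Onset threshold (degrees) to which the
#'   ground-truth tB/tE crossings refer (default 2, the segmentation
#'   default).
#' @param apex_entry_speed Angular speed entering the apex turnaround,
#'   deg/s (default 100, capped at 90% of the adjoining segments' natural
#'   minimum-jerk peak speed).
#' @param apex_cap_s Turnaround duration, seconds (default 0.03).
#' @param pre_s,post_s Rest padding before contact / after table contact.
#' @param rate_hz Sampling rate (default 87).
#' @param seed Integer seed; every random draw is derived from it.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(phase_s = c(0.34, 1.10, 1.11),
                         apex_angle_deg = 60,
                         n_movement_units = 2,
                         contact_impulse = 0.5,
                         impulse_width_s = 0.03,
                         noise_acc_sigma = 0.005,
                         noise_angle_sigma = 0.5,
                         path_length_mm = 0,
                         onset_angle_delta = 2,
                         apex_entry_speed = 100,
                         apex_cap_s = 0.03,
                         pre_s = 0.8, post_s = 0.6,
                         rate_hz = 87, seed = 1) {
  if (any(phase_s <= 0)) abort_parameter("phase durations must be > 0")
  if (n_movement_units < 1) abort_parameter("n_movement_units must be >= 1")
  if (noise_acc_sigma < 0 || noise_angle_sigma < 0) {
    abort_parameter("noise SDs must be >= 0")
  }
  structure(as.list(environment()), class = "trial_config")
}

# quintic polynomial on [0, T] with position/velocity/acceleration boundary
# conditions; returns function(t) -> position
quintic <- function(T, p0, v0, a0, p1, v1, a1) {
  M <- rbind(
    c(1, 0, 0, 0, 0, 0),
    c(0, 1, 0, 0, 0, 0),
    c(0, 0, 2, 0, 0, 0),
    c(1, T, T^2, T^3, T^4, T^5),
    c(0, 1, 2 * T, 3 * T^2, 4 * T^3, 5 * T^4),
    c(0, 0, 2, 6 * T, 12 * T^2, 20 * T^3))
  cf <- solve(M, c(p0, v0, a0, p1, v1, a1))
  function(t) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3 + cf[5] * t^4 + cf[6] * t^5
}

# piecewise clean angle profile; returns list(theta = function(t),
# t_move, tC, lag) with the movement-start time t_move such that the
# delta-crossing falls exactly at tB
build_angle_profile <- function(cfg, tB) {
  A <- cfg$apex_angle_deg
  n <- cfg$n_movement_units
  T_t <- cfg$phase_s[2]
  T_r <- cfg$phase_s[3]
  d <- cfg$apex_cap_s
  delta <- cfg$onset_angle_delta
  if (A / n <= delta) abort_parameter("apex angle too small for the onset threshold")

  mj <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5     # minimum-jerk shape
  mj_v <- function(u) 30 * u^2 - 60 * u^3 + 30 * u^4  # its derivative

  # a minimum-jerk bump truncated in time on its deceleration side so that
  # it covers displacement `a` in duration `w` and ends still moving at
  # speed ve <= ve_max (the apex cap picks the motion up from there); the
  # early rise is a genuine minimum-jerk start, so the onset crossing stays
  # prompt. Solves A_p * mj(u) = a, A_p * mj_v(u) * u / w = ve, T_p = w / u.
  trunc_minjerk <- function(a, w, ve) {
    cc <- ve * w / a
    u <- stats::uniroot(function(u) mj_v(u) * u / mj(u) - cc,
                        c(0.5, 1 - 1e-9), tol = 1e-12)$root
    A_p <- a / mj(u)
    T_p <- w / u
    list(fn = function(t) A_p * mj(t / T_p), dur = w,
         ve = A_p * mj_v(u) / T_p, A_p = A_p, T_p = T_p)
  }
  T_ret <- T_r - d / 2

  # segment builders for a given sub-segment duration w
  make_segments <- function(w) {
    w_f <- w - d / 2               # truncated final segment duration
    if (w_f <= 0.08) {
      abort_parameter("movement units too many for the transport duration: peaks would overlap")
    }
    # one entry speed shared by the transport-final and return segments so
    # the cap is symmetric; kept below 90% of each segment's natural
    # minimum-jerk peak (truncation must land on the deceleration side).
    # The cap displacement (< 1 degree) feeds back on the segment
    # amplitude; one fixed-point refinement suffices.
    a_seg <- A / n
    h_cap <- 0
    for (it in 1:2) {
      ve <- min(cfg$apex_entry_speed,
                0.9 * 1.875 * a_seg / w_f,
                0.9 * 1.875 * (A - h_cap) / T_ret)
      fin <- trunc_minjerk(a_seg, w_f, ve)
      h_cap <- ve * d / 4          # displacement of each cap half
      a_seg <- (A - h_cap) / n
    }
    segs <- list()
    for (i in seq_len(n)) {
      if (i < n) {
        segs[[i]] <- list(dur = w, fn = quintic(w, 0, 0, 0, a_seg, 0, 0))
      } else {
        segs[[i]] <- fin
      }
    }
    attr(segs, "ve") <- ve
    attr(segs, "h_cap") <- h_cap
    attr(segs, "a_seg") <- a_seg
    segs
  }
  # crossing lag of the first segment at threshold delta, for duration w
  lag_for <- function(w) {
    s1 <- make_segments(w)[[1]]
    stats::uniroot(function(t) s1$fn(t) - delta, c(1e-9, s1$dur),
                   tol = 1e-10)$root
  }
  # choose w so that apex lands at tB + T_t: n*w - lag(w) = T_t
  w <- stats::uniroot(function(w) n * w - lag_for(w) - T_t,
                      c(T_t / n + 1e-6, (T_t + 2) / n), tol = 1e-10,
                      extendInt = "upX")$root
  segs <- make_segments(w)
  ve <- attr(segs, "ve")
  h_cap <- attr(segs, "h_cap")
  a_seg <- attr(segs, "a_seg")
  kap <- 2 * ve / d
  lag <- lag_for(w)
  t_move <- tB - lag
  tC <- t_move + n * w             # apex (cap vertex)
  # return: the transport-final bump mirrored in time, so it leaves the cap
  # at speed -ve and decelerates minimum-jerk-style to rest at table contact
  rb <- trunc_minjerk(A - h_cap, T_ret, ve)
  ret_fn <- function(t) rb$fn(T_ret - t)

  starts <- t_move + c(0, cumsum(vapply(segs, `[[`, numeric(1), "dur")))
  theta <- function(t) {
    out <- numeric(length(t))
    base <- 0
    for (i in seq_len(n)) {
      sel <- t >= starts[i] & t < starts[i + 1]
      out[sel] <- base + segs[[i]]$fn(t[sel] - starts[i])
      base <- base + a_seg
    }
    # parabolic cap around the apex
    sel <- t >= tC - d / 2 & t < tC + d / 2
    out[sel] <- A - kap * (t[sel] - tC)^2 / 2
    # return segment
    sel <- t >= tC + d / 2 & t < tC + d / 2 + T_ret
    out[sel] <- ret_fn(t[sel] - tC - d / 2)
    out[t >= tC + d / 2 + T_ret] <- 0
    out[t < t_move] <- 0
    out
  }
  # ground-truth return crossing tE: theta falls below delta on the return
  tE <- stats::uniroot(function(t) theta(t) - delta,
                       c(tC + d / 2 + 1e-6, tC + d / 2 + T_ret - 1e-6),
                       tol = 1e-10)$root
  list(theta = theta, t_move = t_move, tC = tC, tE = tE, lag = lag)
}

raised_cosine <- function(t, center, width, amp) {
  out <- numeric(length(t))
  sel <- abs(t - center) < width / 2
  out[sel] <- amp / 2 * (1 + cos(2 * pi * (t[sel] - center) / width))
  out
}

#' Generate one synthetic trial with ground truth
#'
#' @param cfg A [trial_config()].
#' @return List with `trace` (an [imu_trace()]), `truth` (list: `events` as
#'   [task_events()], `true_units`, `true_path` tibble of the transport
#'   translation in mm, `theta_clean`, `config`).
#' @examples
#' s <- synth_trial(trial_config(seed = 7))
#' segment_trial(s$trace)$events$tC - s$truth$events$tC
#' @export
synth_trial <- function(cfg = trial_config()) {
  rate <- cfg$rate_hz
  acc_s <- cfg$phase_s[1]
  tA <- round(cfg$pre_s * rate) / rate
  tB <- tA + acc_s
  prof <- build_angle_profile(cfg, tB)
  if (prof$t_move < tA) {
    abort_parameter(sprintf(
      "accommodation %.3f s is shorter than the onset-crossing lag %.3f s",
      acc_s, prof$lag), lag = prof$lag)
  }
  tC <- prof$tC
  tD <- round((tC + cfg$phase_s[3]) * rate) / rate
  total <- tD + cfg$post_s
  t <- seq(0, total, by = 1 / rate)
  n <- length(t)

  theta <- prof$theta(t)
  # world-frame linear acceleration: contact impulses (+x) and optional
  # minimum-jerk translation in the sagittal plane (x forward, z up)
  imp <- raised_cosine(t, tA, cfg$impulse_width_s, cfg$contact_impulse) +
    raised_cosine(t, tD, cfg$impulse_width_s, cfg$contact_impulse)
  ax_w <- imp
  az_w <- numeric(n)
  true_path <- NULL
  if (cfg$path_length_mm > 0) {
    D <- cfg$path_length_mm / 1000
    dir <- c(0.6, 0.8)  # forward and up components of the reach
    Tt <- tC - tB
    tau <- pmin(pmax((t - tB) / Tt, 0), 1)
    s_acc <- (60 * tau - 180 * tau^2 + 120 * tau^3) / Tt^2  # min-jerk accel
    s_acc[t < tB | t > tC] <- 0
    Tr <- tD - tC
    tau_r <- pmin(pmax((t - tC) / Tr, 0), 1)
    r_acc <- -(60 * tau_r - 180 * tau_r^2 + 120 * tau_r^3) / Tr^2
    r_acc[t < tC | t > tD] <- 0
    a_tr <- D * (s_acc + r_acc)
    ax_w <- ax_w + dir[1] * a_tr
    az_w <- az_w + dir[2] * a_tr
    s_pos <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    sel <- t >= tB & t <= tC
    true_path <- tibble::tibble(
      t = t[sel],
      x = dir[1] * cfg$path_length_mm * s_pos[sel],
      y = dir[2] * cfg$path_length_mm * s_pos[sel])
  }

  trace <- withr::with_seed(cfg$seed, {
    eY <- theta + stats::rnorm(n, 0, cfg$noise_angle_sigma)
    eX <- stats::rnorm(n, 0, cfg$noise_angle_sigma)
    eZ <- stats::rnorm(n, 0, cfg$noise_angle_sigma)
    R <- euler_to_rot(eX, eY, eZ)
    f <- rot_apply_t(R, ax_w, numeric(n), az_w + GRAVITY_MS2)
    gy_clean <- c(0, diff(theta)) * rate
    tibble::tibble(
      t = t,
      ax = f$x + stats::rnorm(n, 0, cfg$noise_acc_sigma),
      ay = f$y + stats::rnorm(n, 0, cfg$noise_acc_sigma),
      az = f$z + stats::rnorm(n, 0, cfg$noise_acc_sigma),
      gx = stats::rnorm(n, 0, 0.2),
      gy = gy_clean + stats::rnorm(n, 0, 0.2),
      gz = stats::rnorm(n, 0, 0.2),
      eulerX = eX, eulerY = eY, eulerZ = eZ)
  })
  trace <- imu_trace(trace, rate_hz = rate)

  events <- task_events(tA = tA, tB = tB, tC = tC, tD = tD, tE = prof$tE,
                        t_end = tD, criterion_end = "table_contact")
  list(trace = trace,
       truth = list(events = events,
                    true_units = cfg$n_movement_units,
                    true_path = true_path,
                    theta_clean = tibble::tibble(t = t, eulerY = theta),
                    config = cfg))
}

#' Write a synthetic (or real) trial to the canonical CSV format
#'
#' Convenience wrapper pairing [synth_trial()] with [write_imu_text()].
#'
#' @param trial A list with a `trace` element, or an [imu_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  trace <- if (inherits(trial, "imu_trace")) trial else trial$trace
  write_imu_text(trace, path)
}
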
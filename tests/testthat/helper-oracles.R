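# Independent oracles and fixture builders used across the suite.

# Brute-force movement-unit count: dynamic program over the alternating
# extrema sequence maximizing the number of completed
# (drop > thr, then rise > thr) cycles; a unit may start at any position
# where a rise was confirmed. Independent of the hysteresis scan in the
# package.
oracle_movement_units <- function(x, thr) {
  if (max(x) == min(x)) return(if (max(x) > 0) 1L else 0L)
  x <- x[c(TRUE, diff(x) != 0)]
  d <- sign(diff(x))
  turn <- which(diff(d) != 0) + 1
  v <- x[unique(c(1, turn, length(x)))]
  m <- length(v)
  memo <- rep(NA_integer_, m + 1)
  cycles_from <- function(i) {
    if (i > m) return(0L)
    if (!is.na(memo[i])) return(memo[i])
    best <- 0L
    if (i < m) {
      runmax <- v[i]
      for (j in (i + 1):m) {
        runmax <- max(runmax, v[j])
        if (runmax - v[j] > thr) {
          # drop confirmed at j; any later r with rise > thr completes a cycle
          runmin <- v[j]
          if (j < m) {
            for (r in (j + 1):m) {
              runmin <- min(runmin, v[r])
              if (v[r] - runmin > thr) {
                best <- max(best, 1L + cycles_from(r))
              }
            }
          }
        }
      }
    }
    memo[i] <<- best
    best
  }
  1L + cycles_from(1L)
}

# random piecewise-linear non-negative speed profile
random_speed_profile <- function(seed, n_knots = NULL, len = 80, vmax = 300) {
  withr::with_seed(seed, {
    if (is.null(n_knots)) n_knots <- sample(4:12, 1)
    knots <- stats::runif(n_knots, 0, vmax)
    stats::approx(seq_along(knots), knots, n = len)$y
  })
}

# random orientation as Euler Z-Y-X angles (degrees)
random_euler <- function() {
  c(stats::runif(1, -180, 180), stats::runif(1, -89, 89), stats::runif(1, -180, 180))
}

# static imu_trace at the given Euler orientation: the specific force is
# gravity rotated into the sensor frame
static_trace_at <- function(euler, n = 40, rate = 87) {
  R <- graspkin:::euler_to_rot(euler[1], euler[2], euler[3])
  f <- graspkin:::rot_apply_t(R, 0, 0, graspkin:::GRAVITY_MS2)
  imu_trace(tibble::tibble(
    t = (seq_len(n) - 1) / rate,
    ax = rep(f$x, n), ay = rep(f$y, n), az = rep(f$z, n),
    gx = 0, gy = 0, gz = 0,
    eulerX = euler[1], eulerY = euler[2], eulerZ = euler[3]),
    rate_hz = rate)
}

# minimal valid trace with prescribed channels defaulting to zero
make_trace <- function(t, eulerY = 0, ax = 0, ay = 0, az = 9.80665, rate = 87) {
  n <- length(t)
  imu_trace(tibble::tibble(
    t = t,
    ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
    gx = 0, gy = 0, gz = 0,
    eulerX = 0, eulerY = rep_len(eulerY, n), eulerZ = 0), rate_hz = rate)
}

# lin_acc_trace built directly from a resultant profile (x-axis carries it)
make_lin <- function(t, resultant, rate = 87) {
  out <- tibble::tibble(t = t, lx = resultant, ly = 0, lz = 0,
                        resultant = abs(resultant))
  attr(out, "rate_hz") <- rate
  class(out) <- c("lin_acc_trace", class(tibble::tibble()))
  out
}

expect_graspkin_error <- function(expr, class) {
  expect_error(expr, class = paste0("graspkin_error_", class))
}
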
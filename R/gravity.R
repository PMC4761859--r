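# Orientation handling and gravity compensation.
#
# Conventions (recorded here because the sensor vendor does not publish one):
# the orientation channels give the sensor-to-world rotation R; Euler angles
# are intrinsic Z-Y-X, R = Rz(eulerZ) %*% Ry(eulerY) %*% Rx(eulerX), degrees;
# the quaternion is (qw, qx, qy, qz), scalar first. The accelerometer
# measures specific force f in the sensor frame, so at rest a level device
# reads (0, 0, g). World linear acceleration is a = R f - (0, 0, g).

GRAVITY_MS2 <- 9.80665

# vectorized rotation-matrix elements from Euler Z-Y-X intrinsic (degrees);
# returns list of 9 numeric vectors r11..r33
euler_to_rot <- function(ex, ey, ez) {
  d <- pi / 180
  cx <- cos(ex * d); sx <- sin(ex * d)
  cy <- cos(ey * d); sy <- sin(ey * d)
  cz <- cos(ez * d); sz <- sin(ez * d)
  list(
    r11 = cz * cy, r12 = cz * sy * sx - sz * cx, r13 = cz * sy * cx + sz * sx,
    r21 = sz * cy, r22 = sz * sy * sx + cz * cx, r23 = sz * sy * cx - cz * sx,
    r31 = -sy,     r32 = cy * sx,                r33 = cy * cx
  )
}

quat_to_rot <- function(qw, qx, qy, qz) {
  n <- sqrt(qw^2 + qx^2 + qy^2 + qz^2)
  qw <- qw / n; qx <- qx / n; qy <- qy / n; qz <- qz / n
  list(
    r11 = 1 - 2 * (qy^2 + qz^2), r12 = 2 * (qx * qy - qz * qw), r13 = 2 * (qx * qz + qy * qw),
    r21 = 2 * (qx * qy + qz * qw), r22 = 1 - 2 * (qx^2 + qz^2), r23 = 2 * (qy * qz - qx * qw),
    r31 = 2 * (qx * qz - qy * qw), r32 = 2 * (qy * qz + qx * qw), r33 = 1 - 2 * (qx^2 + qy^2)
  )
}

trace_rotations <- function(trace) {
  if (all(quat_cols %in% names(trace))) {
    quat_to_rot(trace$qw, trace$qx, trace$qy, trace$qz)
  } else if (all(euler_cols %in% names(trace))) {
    euler_to_rot(trace$eulerX, trace$eulerY, trace$eulerZ)
  } else {
    abort_capability("gravity compensation needs an orientation channel (quaternion or Euler angles)")
  }
}

# apply R (as element list) to column vectors vx,vy,vz
rot_apply <- function(R, vx, vy, vz) {
  list(x = R$r11 * vx + R$r12 * vy + R$r13 * vz,
       y = R$r21 * vx + R$r22 * vy + R$r23 * vz,
       z = R$r31 * vx + R$r32 * vy + R$r33 * vz)
}

# apply R^T (world -> sensor)
rot_apply_t <- function(R, vx, vy, vz) {
  list(x = R$r11 * vx + R$r21 * vy + R$r31 * vz,
       y = R$r12 * vx + R$r22 * vy + R$r32 * vz,
       z = R$r13 * vx + R$r23 * vy + R$r33 * vz)
}

#' Gravity-compensated linear acceleration
#'
#' Rotates the measured specific force into the world frame using the
#' trace's orientation (quaternion preferred, else Euler angles) and
#' subtracts standard gravity (0, 0, 9.80665) m/s². The resultant column is
#' the Euclidean magnitude of the three world components; contact events are
#' detected on it.
#'
#' @param trace An [imu_trace()], normally already low-pass filtered.
#' @return A tibble of class `lin_acc_trace` with columns
#'   `t, lx, ly, lz, resultant`.
#' @export
gravity_compensate <- function(trace) {
  R <- trace_rotations(trace)
  w <- rot_apply(R, trace$ax, trace$ay, trace$az)
  lx <- w$x; ly <- w$y; lz <- w$z - GRAVITY_MS2
  out <- tibble::tibble(t = trace$t, lx = lx, ly = ly, lz = lz,
                        resultant = sqrt(lx^2 + ly^2 + lz^2))
  attr(out, "rate_hz") <- imu_rate(trace)
  class(out) <- c("lin_acc_trace", class(tibble::tibble()))
  out
}

#' @export
print.lin_acc_trace <- function(x, ...) {
  cat(sprintf("<lin_acc_trace> %d samples, peak resultant %.4g m/s^2\n",
              nrow(x), max(x$resultant)))
  NextMethod()
}
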
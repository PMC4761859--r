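#' Construct and validate an IMU trial trace
#'
#' An `imu_trace` is a tibble with one row per sample and canonical columns
#' `t` (seconds, strictly increasing), `ax, ay, az` (specific force, m/s²,
#' sensor frame), `gx, gy, gz` (angular velocity, deg/s), optional
#' `mx, my, mz` (magnetometer, arbitrary units), `eulerX, eulerY, eulerZ`
#' (degrees) and/or a unit quaternion `qw, qx, qy, qz` describing the
#' sensor-to-world rotation. `eulerY` is the tilt of the glass in the
#' sagittal plane, the primary channel for movement onset/apex/return
#' detection.
#'
#' @param data A data frame holding the canonical columns.
#' @param rate_hz Nominal sampling rate in Hz (the device streams at 87 Hz).
#' @return A tibble of class `imu_trace` with attribute `rate_hz`.
#' @examples
#' tr <- synth_trial(trial_config(seed = 1))$trace
#' dplyr::glimpse(tr)
#' @export
imu_trace <- function(data, rate_hz = 87) {
  data <- tibble::as_tibble(data)
  validate_imu_trace(data, rate_hz)
  attr(data, "rate_hz") <- rate_hz
  class(data) <- c("imu_trace", class(tibble::tibble()))
  data
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples @ %g Hz, %.3f-%.3f s\n",
              nrow(x), imu_rate(x), x$t[1], x$t[nrow(x)]))
  NextMethod()
}

#' Nominal sampling rate of a trace
#' @param trace An `imu_trace`.
#' @return Rate in Hz.
#' @export
imu_rate <- function(trace) {
  r <- attr(trace, "rate_hz")
  if (is.null(r)) {
    # attribute may be shed by data-frame verbs; fall back to the timestamps
    r <- 1 / stats::median(diff(trace$t))
  }
  r
}

mandatory_cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
euler_cols <- c("eulerX", "eulerY", "eulerZ")
quat_cols <- c("qw", "qx", "qy", "qz")

validate_imu_trace <- function(data, rate_hz) {
  missing <- setdiff(mandatory_cols, names(data))
  if (length(missing) > 0) {
    abort_format(paste0("missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  has_euler <- all(euler_cols %in% names(data))
  has_quat <- all(quat_cols %in% names(data))
  if (!has_euler && !has_quat) {
    abort_format("an orientation channel is required: eulerX/Y/Z or qw/qx/qy/qz")
  }
  if (nrow(data) < 2) {
    abort_validation("an imu_trace needs at least 2 samples")
  }
  dt <- diff(data$t)
  if (any(dt <= 0)) {
    idx <- which(dt <= 0)[1]
    abort_validation(sprintf(
      "timestamps must be strictly increasing; first violation at index %d (t[%d] = %g, t[%d] = %g)",
      idx, idx, data$t[idx], idx + 1, data$t[idx + 1]))
  }
  med_dt <- stats::median(dt)
  if (abs(med_dt - 1 / rate_hz) > 0.2 / rate_hz) {
    abort_validation(sprintf(
      "median sample interval %.4f s is not within 20%% of nominal 1/%g Hz",
      med_dt, rate_hz))
  }
  if (has_quat) {
    qn <- sqrt(data$qw^2 + data$qx^2 + data$qy^2 + data$qz^2)
    bad <- which(abs(qn - 1) > 1e-3)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "quaternion norm deviates from 1 by more than 1e-3 at %d sample(s), first at index %d",
        length(bad), bad[1]))
    }
  }
  invisible(data)
}

#' Column-map dialect for reading IMU text logs
#'
#' The motion sensor firmware writes trials as delimited text, but the column
#' layout varies between firmware versions and export tools. A dialect names,
#' for each canonical channel, the column (by header name or 1-based index)
#' holding it, plus the delimiter and the angle unit used in the file.
#'
#' @param columns Named character or integer vector mapping canonical names
#'   (`t`, `ax`, ..., `eulerY`, ..., `qw`, ...) to file columns. Defaults to
#'   identity naming for the canonical layout written by [write_imu_text()].
#' @param delim Field delimiter: `","`, `"\t"`, or `"whitespace"`.
#' @param angle_unit `"deg"` or `"rad"` for Euler angles in the file.
#' @param header Does the file carry a header row?
#' @return A list of class `imu_dialect`.
#' @export
imu_dialect <- function(columns = NULL, delim = ",", angle_unit = "deg",
                        header = TRUE) {
  angle_unit <- match.arg(angle_unit, c("deg", "rad"))
  if (is.null(columns)) {
    canon <- c(mandatory_cols, euler_cols, quat_cols, c("mx", "my", "mz"))
    columns <- stats::setNames(canon, canon)
  }
  structure(list(columns = columns, delim = delim,
                 angle_unit = angle_unit, header = header),
            class = "imu_dialect")
}

#' Read an IMU trial from a delimited text log
#'
#' @param path Path to the text file.
#' @param dialect An [imu_dialect()] describing the column layout.
#' @param rate_hz Nominal sampling rate (default 87 Hz).
#' @return An [imu_trace()].
#' @export
read_imu_text <- function(path, dialect = imu_dialect(), rate_hz = 87) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- switch(dialect$delim,
    "whitespace" = readr::read_table(path, col_names = dialect$header,
                                     show_col_types = FALSE, progress = FALSE),
    readr::read_delim(path, delim = dialect$delim, col_names = dialect$header,
                      show_col_types = FALSE, progress = FALSE))
  out <- list()
  for (canon in names(dialect$columns)) {
    key <- dialect$columns[[canon]]
    col <- if (is.numeric(key)) {
      if (key <= ncol(raw)) raw[[key]] else NULL
    } else {
      if (key %in% names(raw)) raw[[key]] else NULL
    }
    if (is.null(col)) {
      if (canon %in% mandatory_cols) {
        abort_format(sprintf("mandatory column '%s' (mapped to '%s') not found in %s",
                             canon, as.character(key), path))
      }
      next
    }
    out[[canon]] <- as.numeric(col)
  }
  out <- tibble::as_tibble(out)
  if (!all(euler_cols %in% names(out)) && !all(quat_cols %in% names(out))) {
    abort_format("no orientation columns (eulerX/Y/Z or qw/qx/qy/qz) found; check the dialect map")
  }
  if (dialect$angle_unit == "rad" && all(euler_cols %in% names(out))) {
    out[euler_cols] <- lapply(out[euler_cols], function(v) v * 180 / pi)
  }
  imu_trace(out, rate_hz = rate_hz)
}

#' Write a trace in the canonical trial CSV format
#'
#' Fixed header `t,ax,ay,az,gx,gy,gz[,mx,my,mz],eulerX,eulerY,eulerZ[,qw,qx,qy,qz]`,
#' angles in degrees. The representation round-trips through
#' [read_imu_text()] to full double precision.
#'
#' @param trace An [imu_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_text <- function(trace, path) {
  keep <- intersect(c(mandatory_cols, c("mx", "my", "mz"), euler_cols, quat_cols),
                    names(trace))
  readr::write_csv(tibble::as_tibble(trace)[keep], path, progress = FALSE)
  invisible(path)
}
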
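# Zero-phase low-pass conditioning. The acceleration channels are filtered
# before event detection; angle channels can be included so that onset/apex
# detection sees the same bandwidth.

# forward-backward Butterworth with odd-reflection padding at both ends;
# padding suppresses the start-up transient of the recursive filter so that
# a windowed in-band sinusoid passes with <1e-7 error.
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * 30)
  head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xx <- c(head_ref, x, tail_ref)
  y <- signal::filter(filt, xx)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[seq(pad + 1, pad + n)]
}

#' Zero-phase low-pass filter a trace
#'
#' Applies a Butterworth low-pass forward and backward (no group delay) to
#' the acceleration channels, and optionally to every numeric channel. The
#' device's event-detection chain filters acceleration at 15 Hz before
#' gravity compensation.
#'
#' @param trace An [imu_trace()].
#' @param cutoff_hz Cutoff frequency, Hz (default 15). Must be below the
#'   Nyquist frequency.
#' @param order Butterworth order of each pass (default 2); the
#'   forward-backward application doubles it, giving a fourth-order
#'   zero-phase response at the default. Higher per-pass orders ring more
#'   on contact impulses and their leading sidelobe can masquerade as an
#'   earlier acceleration peak.
#' @param channels `"acc"` to filter only `ax, ay, az`; `"all"` to filter
#'   every channel except `t`.
#' @return A filtered [imu_trace()] of the same length.
#' @export
lowpass <- function(trace, cutoff_hz = 15, order = 2, channels = c("acc", "all")) {
  channels <- match.arg(channels)
  rate <- imu_rate(trace)
  if (cutoff_hz >= rate / 2) {
    abort_parameter(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                            cutoff_hz, rate / 2))
  }
  if (cutoff_hz <= 0) abort_parameter("cutoff must be positive")
  filt <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  cols <- if (channels == "acc") c("ax", "ay", "az") else
    setdiff(names(trace)[vapply(trace, is.numeric, logical(1))], "t")
  cols <- intersect(cols, names(trace))
  out <- tibble::as_tibble(trace)
  for (cl in cols) out[[cl]] <- filtfilt_padded(filt, out[[cl]])
  if (all(quat_cols %in% names(out)) && channels == "all") {
    # renormalize the filtered quaternion
    qn <- sqrt(out$qw^2 + out$qx^2 + out$qy^2 + out$qz^2)
    for (cl in quat_cols) out[[cl]] <- out[[cl]] / qn
  }
  imu_trace(out, rate_hz = rate)
}

#' Resample a trace onto a uniform time grid
#'
#' Linear interpolation of every channel onto `seq(t[1], t[n], by = 1/rate_hz)`.
#' Integration-based metrics (path reconstruction, activity counts) assume
#' uniform sampling; recordings with timestamp jitter should pass through
#' here first.
#'
#' @param trace An [imu_trace()].
#' @param rate_hz Target rate; defaults to the trace's nominal rate.
#' @return A uniformly sampled [imu_trace()].
#' @export
resample_uniform <- function(trace, rate_hz = imu_rate(trace)) {
  tt <- seq(trace$t[1], trace$t[nrow(trace)], by = 1 / rate_hz)
  out <- tibble::as_tibble(lapply(
    tibble::as_tibble(trace)[setdiff(names(trace), "t")],
    function(v) stats::approx(trace$t, v, xout = tt)$y))
  out <- dplyr::bind_cols(tibble::tibble(t = tt), out)
  imu_trace(out, rate_hz = rate_hz)
}
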
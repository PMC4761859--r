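#' Parameters for task-event detection
#'
#' Thresholds of the five-event segmentation of a drinking-simulation trial:
#' A (first hand-object contact), B (movement onset), C (apex at the mouth),
#' D (table contact) and E (return to initial orientation).
#'
#' @param contact_threshold Resultant-acceleration threshold, m/s². The
#'   device's published value is 0.02 m/s² on the low-pass-filtered,
#'   gravity-compensated resultant.
#' @param onset_angle_delta Degrees the sagittal Euler angle must depart from
#'   its pre-contact baseline to call movement onset. The source method used
#'   an unstated empiric threshold; 2.0 degrees is this package's default and
#'   is echoed into all outputs.
#' @param return_angle_delta Degrees below which the angle counts as returned
#'   (default: same as `onset_angle_delta`).
#' @param baseline_window_s Window before contact over which the baseline
#'   angle is taken as the median (default 0.5 s).
#' @param peak_min_separation_s Dead time after the apex before a second
#'   acceleration peak may be read as table contact (default 0.3 s).
#' @param end_rule Which event ends the trial: `"table_contact"` (the
#'   published choice), `"orientation_return"`, or `"earliest"`.
#' @param debounce_samples Consecutive samples the onset crossing must hold
#'   (default 3) so single noisy samples do not trigger.
#' @param onset_smooth_hz Extra zero-phase smoothing applied to the
#'   sagittal angle before evaluating the onset and return crossings
#'   (default 6 Hz). The crossing estimate's jitter is the angle noise
#'   divided by the angle slope at the threshold, and the slope there is
#'   low-frequency; the apex search keeps the full conditioning bandwidth
#'   so the turnaround stays sharp.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(contact_threshold = 0.02,
                                onset_angle_delta = 2.0,
                                return_angle_delta = onset_angle_delta,
                                baseline_window_s = 0.5,
                                peak_min_separation_s = 0.3,
                                end_rule = c("table_contact", "orientation_return", "earliest"),
                                debounce_samples = 3L,
                                onset_smooth_hz = 6) {
  end_rule <- match.arg(end_rule)
  vals <- c(contact_threshold, onset_angle_delta, return_angle_delta,
            baseline_window_s, peak_min_separation_s)
  if (any(vals <= 0)) abort_parameter("all segmentation thresholds must be > 0")
  structure(list(contact_threshold = contact_threshold,
                 onset_angle_delta = onset_angle_delta,
                 return_angle_delta = return_angle_delta,
                 baseline_window_s = baseline_window_s,
                 peak_min_separation_s = peak_min_separation_s,
                 end_rule = end_rule,
                 debounce_samples = as.integer(debounce_samples),
                 onset_smooth_hz = onset_smooth_hz),
            class = "segmentation_params")
}

# topographic prominence of peaks at indices pk: height above the highest
# saddle separating the peak from higher terrain on either side
peak_prominence <- function(x, pk) {
  vapply(pk, function(i) {
    left <- x[seq_len(i - 1)]
    right <- if (i < length(x)) x[(i + 1):length(x)] else numeric(0)
    saddle <- function(side) {
      higher <- which(side > x[i])  # strictly: equal height is the same massif
      if (length(higher) == 0) return(min(c(side, x[i])))
      min(side[seq(higher[length(higher)], length(side))])
    }
    sl <- if (length(left) == 0) -Inf else saddle(left)
    sr <- if (length(right) == 0) -Inf else saddle(rev(right))
    x[i] - max(min(sl, x[i]), min(sr, x[i]), na.rm = TRUE)
  }, numeric(1))
}

# first local maximum after t0 exceeding thr in both height and prominence,
# refined to the highest peak inside the ringing merge window. A zero-phase
# filter spreads one physical impact into a main lobe flanked by sidelobes
# within roughly +/- 3 / cutoff of it; the prominence requirement rejects
# sidelobes outright and the merge window resolves the borderline ones in
# favor of the main lobe. Separate contacts are farther apart than the
# window by the dead-time rule.
first_qualifying_peak <- function(t, x, thr, t0 = -Inf, merge_window_s = 0.1) {
  pk <- local_maxima(x)
  pk <- pk[t[pk] > t0 & x[pk] > thr]
  if (length(pk) == 0) return(NA_real_)
  prom <- peak_prominence(x, pk)
  pk <- pk[prom > thr]
  if (length(pk) == 0) return(NA_real_)
  first <- pk[1]
  window <- pk[t[pk] >= t[first] & t[pk] <= t[first] + merge_window_s]
  t[window[which.max(x[window])]]
}

# indices of local maxima; a flat-topped maximum reports its first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # compare to previous distinct value on the left, next value on the right
  rises <- c(FALSE, diff(x) > 0)
  falls <- c(diff(x) < 0, FALSE)
  # run-length pass so plateaus inherit the left rise and right fall
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (k in seq_along(r$values)) {
    left_up <- k > 1 && r$values[k - 1] < r$values[k]
    right_down <- k < length(r$values) && r$values[k + 1] < r$values[k]
    if (left_up && right_down) out <- c(out, starts[k])
  }
  out
}

#' Detect first hand-object contact (event A)
#'
#' First local maximum of the gravity-compensated resultant acceleration
#' exceeding the contact threshold: the acceleration peak when the hand
#' first touches the glass.
#'
#' @param lin A `lin_acc_trace` from [gravity_compensate()] on a
#'   low-pass-filtered trace.
#' @param params [segmentation_params()].
#' @return Contact time `tA` in seconds.
#' @export
detect_contact <- function(lin, params = segmentation_params()) {
  tA <- first_qualifying_peak(lin$t, lin$resultant, params$contact_threshold)
  if (is.na(tA)) {
    abort_event(sprintf("no resultant-acceleration peak exceeds %g m/s^2 (event A not found)",
                        params$contact_threshold))
  }
  tA
}

# median sagittal angle over the baseline window preceding tA
euler_baseline <- function(trace, tA, params = segmentation_params()) {
  sel <- trace$t >= tA - params$baseline_window_s & trace$t < tA
  if (!any(sel)) sel <- trace$t <= tA
  stats::median(trace$eulerY[sel])
}

# the additionally smoothed angle channel used for the B/E crossings
onset_angle <- function(trace, params) {
  if (is.null(params$onset_smooth_hz) ||
        params$onset_smooth_hz >= imu_rate(trace) / 2) {
    return(trace$eulerY)
  }
  lowpass(trace, cutoff_hz = params$onset_smooth_hz, channels = "all")$eulerY
}

#' Detect movement onset (event B)
#'
#' First time after contact at which the sagittal Euler angle departs from
#' its pre-contact baseline by more than the onset threshold and stays
#' beyond it for the debounce length.
#'
#' @param trace An [imu_trace()] with `eulerY`.
#' @param tA Contact time from [detect_contact()].
#' @param params [segmentation_params()].
#' @return Onset time `tB` (seconds), with the baseline used attached as
#'   attribute `baseline`.
#' @export
detect_onset <- function(trace, tA, params = segmentation_params()) {
  if (tA < trace$t[1] || tA > trace$t[nrow(trace)]) {
    abort_parameter("tA lies outside the trace time span")
  }
  sm <- onset_angle(trace, params)
  base <- stats::median(sm[trace$t >= tA - params$baseline_window_s & trace$t < tA])
  dev <- abs(sm - base) > params$onset_angle_delta
  after <- trace$t >= tA
  idx <- which(dev & after)
  k <- params$debounce_samples
  for (i in idx) {
    if (i + k - 1 <= nrow(trace) && all(dev[i:(i + k - 1)])) {
      return(structure(trace$t[i], baseline = base))
    }
  }
  abort_event("sagittal angle never departs its baseline (event B not found)")
}

#' Detect movement apex (event C)
#'
#' Time of the global maximum of the absolute baseline-referenced sagittal
#' angle after onset: the inversion of the movement when the glass reaches
#' the mouth. Flat maxima report their first sample.
#'
#' @param trace An [imu_trace()].
#' @param tB Onset time.
#' @param baseline Baseline angle (degrees); from [detect_onset()] in the
#'   normal chain.
#' @param params [segmentation_params()].
#' @return Apex time `tC` in seconds.
#' @export
detect_apex <- function(trace, tB, baseline = 0, params = segmentation_params()) {
  sel <- which(trace$t >= tB)
  if (length(sel) < 2) abort_event("no samples after onset (event C not found)")
  dev <- abs(trace$eulerY[sel] - baseline)
  tC <- trace$t[sel[which.max(dev)]]  # which.max takes the first of ties
  tC
}

#' Detect trial end (events D and E)
#'
#' Two end criteria are computed: D, the second acceleration peak (first
#' resultant local maximum above the contact threshold after the apex plus a
#' dead time) marking table contact; and E, the first time the sagittal
#' angle comes back within the return threshold of its baseline. The trial
#' end is chosen by `params$end_rule`; the published choice is table
#' contact.
#'
#' @param trace An [imu_trace()].
#' @param lin Matching `lin_acc_trace`.
#' @param tC Apex time.
#' @param baseline Baseline angle (degrees).
#' @param params [segmentation_params()].
#' @return A list with `tD`, `tE` (either may be `NA`), `t_end`, and
#'   `criterion_end` (`"table_contact"` or `"orientation_return"`).
#' @export
detect_end <- function(trace, lin, tC, baseline = 0, params = segmentation_params()) {
  tD <- first_qualifying_peak(lin$t, lin$resultant, params$contact_threshold,
                              t0 = tC + params$peak_min_separation_s)

  sm <- onset_angle(trace, params)
  sel <- which(trace$t > tC)
  back <- sel[abs(sm[sel] - baseline) < params$return_angle_delta]
  tE <- if (length(back) > 0) trace$t[back[1]] else NA_real_

  if (is.na(tD) && is.na(tE)) {
    abort_event("neither table contact (D) nor orientation return (E) found after the apex")
  }
  choice <- switch(params$end_rule,
    table_contact = if (!is.na(tD)) "table_contact" else "orientation_return",
    orientation_return = if (!is.na(tE)) "orientation_return" else "table_contact",
    earliest = {
      if (is.na(tD)) "orientation_return"
      else if (is.na(tE)) "table_contact"
      else if (tE <= tD) "orientation_return" else "table_contact"
    })
  t_end <- if (choice == "table_contact") tD else tE
  list(tD = tD, tE = tE, t_end = t_end, criterion_end = choice)
}

#' Task events as a one-row tibble
#'
#' @param tA,tB,tC,tD,tE Event times, seconds (`tD`/`tE` may be `NA`).
#' @param t_end Trial end per the end rule.
#' @param criterion_end Which criterion closed the trial.
#' @return One-row tibble of class `task_events`.
#' @export
task_events <- function(tA, tB, tC, tD = NA_real_, tE = NA_real_,
                        t_end = tD, criterion_end = "table_contact") {
  if (!(tA <= tB && tB < tC) || (!is.na(tD) && !(tC < tD))) {
    abort_validation("event times must satisfy tA <= tB < tC < tD")
  }
  ev <- tibble::tibble(tA = tA, tB = tB, tC = tC, tD = tD, tE = tE,
                       t_end = t_end, criterion_end = criterion_end)
  class(ev) <- c("task_events", class(tibble::tibble()))
  ev
}

#' Phase decomposition from events
#'
#' Accommodation = B - A, transport = C - B, return = end - C, with
#' percentages of the total. Percentages always sum to 100.
#'
#' @param events A [task_events()] row.
#' @return One-row tibble of class `phase_decomposition`.
#' @export
phase_decomposition <- function(events) {
  acc <- events$tB - events$tA
  tra <- events$tC - events$tB
  ret <- events$t_end - events$tC
  tot <- acc + tra + ret
  out <- tibble::tibble(
    total_s = tot, accommodation_s = acc, transport_s = tra, return_s = ret,
    accommodation_pct = 100 * acc / tot,
    transport_pct = 100 * tra / tot,
    return_pct = 100 * ret / tot)
  class(out) <- c("phase_decomposition", class(tibble::tibble()))
  out
}

#' Segment a full trial into events and phases
#'
#' Runs the full chain: 15 Hz zero-phase low-pass (all channels), gravity
#' compensation, then events A (contact), B (onset), C (apex), D/E (end).
#'
#' @param trace A raw [imu_trace()] covering one full drinking cycle.
#' @param params [segmentation_params()].
#' @return An object of class `grasp_segmentation`: list with `events`
#'   ([task_events()]), `phases` ([phase_decomposition()]), `params`, and
#'   `baseline` (degrees). Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' s <- synth_trial(trial_config(seed = 2))
#' seg <- segment_trial(s$trace)
#' glance(seg)
#' @export
segment_trial <- function(trace, params = segmentation_params()) {
  stage <- "lowpass"
  res <- tryCatch({
    filt <- lowpass(trace, channels = "all")
    stage <- "gravity_compensate"
    lin <- gravity_compensate(filt)
    stage <- "contact (A)"
    tA <- detect_contact(lin, params)
    stage <- "onset (B)"
    tB <- detect_onset(filt, tA, params)
    base <- attr(tB, "baseline")
    stage <- "apex (C)"
    tC <- detect_apex(filt, as.numeric(tB), base, params)
    stage <- "end (D/E)"
    fin <- detect_end(filt, lin, tC, base, params)
    ev <- task_events(tA, as.numeric(tB), tC, fin$tD, fin$tE,
                      fin$t_end, fin$criterion_end)
    list(events = ev, phases = phase_decomposition(ev),
         params = params, baseline = base,
         filtered = filt, lin = lin)
  }, graspkin_error_event = function(e) {
    abort_event(paste0("segmentation failed at stage '", stage, "': ",
                       conditionMessage(e)))
  })
  structure(res, class = "grasp_segmentation")
}

#' @export
print.grasp_segmentation <- function(x, ...) {
  ev <- x$events
  cat("<grasp_segmentation>\n")
  cat(sprintf("  A %.3f  B %.3f  C %.3f  D %s  E %s s (end: %s)\n",
              ev$tA, ev$tB, ev$tC,
              ifelse(is.na(ev$tD), "-", sprintf("%.3f", ev$tD)),
              ifelse(is.na(ev$tE), "-", sprintf("%.3f", ev$tE)),
              ev$criterion_end))
  ph <- x$phases
  cat(sprintf("  phases: %.3f / %.3f / %.3f s (%.1f%% / %.1f%% / %.1f%%)\n",
              ph$accommodation_s, ph$transport_s, ph$return_s,
              ph$accommodation_pct, ph$transport_pct, ph$return_pct))
  invisible(x)
}
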
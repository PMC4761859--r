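---
title: "Methods: phase segmentation, kinematic metrics and grasp imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase segmentation, kinematic metrics and grasp imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspkin)
```

## The measurement problem

graspkin analyzes trials recorded with an instrumented drinking glass used
to assess upper-limb function in children. The glass carries two sensor
systems:

* an IMU (87 Hz) reporting 3-axis specific force, angular velocity and
  orientation (Euler angles and/or a quaternion), from which one
  reach-transport-return cycle of a simulated "drinking" task is segmented
  and summarized; and
* a camera looking up into a hyperbolic mirror, imaging the full 360° of
  the grasping hand on the transparent cylinder as a bright annulus, from
  which a metric panorama of the hand is computed and the skin segmented.

The trial cycle is partitioned by five key instants: **A** first
hand–object contact, **B** movement onset, **C** apex (glass at the
mouth), **D** table contact, **E** return to the initial orientation.
These induce three phases: accommodation (A→B), transport (B→C) and
return (C→end, with table contact as the default end criterion and
orientation return retained as an alternative).

## Signal conditioning

Acceleration is conditioned with a zero-phase Butterworth low-pass at
15 Hz before event detection. The filter is order 2 per pass, applied
forward and backward — a net fourth-order zero-phase response. We
deliberately do not use a higher per-pass order: an order-4 pass (net 8)
pre-rings on short contact impulses strongly enough that the leading
sidelobe of a 0.5 m/s² impulse exceeds the 0.02 m/s² contact threshold
and would register as a spurious earlier "peak". The forward–backward
pass uses odd-reflection padding at both record ends; the padding is
exact to first order only, so strict no-op refiltering of an in-band
signal holds in the record interior (and for content well below the
corner — at the corner itself a Butterworth necessarily attenuates a few
permille per pass).

Gravity compensation rotates the measured specific force into the world
frame using the unit quaternion when present, else Euler angles in the
intrinsic Z-Y-X convention (the sensor vendor does not publish one; the
convention is a configuration fact recorded here), and subtracts standard
gravity g = 9.80665 m/s². The resultant magnitude of the compensated
acceleration is the contact-detection channel.

## Event detection

* **A (contact)** — first local maximum of the filtered, compensated
  resultant exceeding the contact threshold (default 0.02 m/s²). Two
  robustness refinements: the peak must also exceed the threshold in
  topographic prominence, and qualifying maxima within a 0.1 s merge
  window are treated as one impact with the tallest reported. Both guard
  against the residual sidelobes that any zero-phase filter places around
  an impact; genuinely separate contacts are farther apart than the
  window.
* **B (onset)** — the sagittal Euler angle departs from its pre-contact
  baseline (median over 0.5 s before A) by more than the onset threshold
  (default 2.0°; the original method used an unstated empiric value) and
  stays beyond it for 3 samples. The crossing is evaluated on an angle
  copy additionally smoothed at 6 Hz: crossing jitter is angle noise
  divided by the angle's slope at the threshold, and the slope there is
  low-frequency content, so the extra smoothing buys precision without
  biasing the crossing materially.
* **C (apex)** — global maximum of the baseline-referenced absolute angle
  after B, on the full 15 Hz conditioning bandwidth (flat maxima report
  their first sample).
* **D (table contact)** — first qualifying resultant peak after C plus a
  0.3 s dead time, same peak rule as A.
* **E (orientation return)** — first time after C the smoothed angle is
  back within the return threshold of baseline.

Phase durations and percentages follow from the events; percentages sum
to 100 by construction.

A known limitation inherited from the published end rule: if the device
translates appreciably during the return, the resultant acceleration of
the movement itself exceeds the 0.02 m/s² threshold long before the table
impact, and the "first peak after the apex" reading of D fires on the
movement's own deceleration. The rule works when contacts dominate the
compensated resultant — which is also how the synthetic study conditions
are posed (rotation plus contact impulses; see below).

## Kinematic metrics

**Movement units.** One unit is an acceleration–deceleration pulse of the
speed profile. Counting uses hysteresis: a new unit opens each time the
speed has dropped from its running maximum by more than the threshold and
then risen from the subsequent running minimum by more than the
threshold; the final deceleration closes the terminal unit, so a single
bell counts once. The speed channel is rotational (|d eulerY/dt|, central
differences), the device's indirect surrogate for endpoint speed; its
published translational threshold is 40 mm/s, and the rotational default
here is 8°/s. Before counting, the angle is smoothed at 3 Hz: unit
structure in this task repeats at ≤ ~2.6 Hz, while differentiating at the
full conditioning bandwidth turns 0.5° orientation noise into ~13°/s of
speed noise — larger than the counting threshold. The 3 Hz value was
calibrated on simulated trials (99–100% exact recovery of the generated
unit count). The counting window is the transport phase, ending at the
apex standstill (the speed minimum adjacent to C), so a 1–2 sample apex
offset cannot leak the first rising sample of the return into the count.

**Straightness index.** Straight-line endpoint distance over traveled arc
length, in (0, 1]. The sagittal path is reconstructed by
double-integrating the compensated acceleration over a phase with
zero-velocity boundary conditions at both ends (the glass rests on the
table and pauses at the mouth), removing the linear velocity drift
between the endpoints before the second integration. With the default
rotation-only simulated trials there is no measurable translation and the
index is reported `NA`; the original device derived it from unspecified
indirect measures, and both the path-based and a rotational surrogate
route are available.

**Activity counts (energy expenditure).** The time-weighted sum of the
compensated resultant over a window — the standard accelerometer
activity-count proxy for physical-activity level. Units are arbitrary
and comparable only within a configuration; counts are additive over
disjoint windows and monotone in movement amplitude.

**Group summaries.** Mean ± SD per group per metric, the shape of the
study's descriptive tables; no inferential statistics.

## The mirror model and panoramic unwrapping

The annular mirror image maps to the cylinder surface (circumference
140 mm; length 100 mm of which the bottom 30 mm band is rejected — the
mirror compresses it into a few low-resolution pixels). The default
radius-to-height calibration interpolates linearly between the inner
radius (cylinder top) and the outer radius (rejected-band boundary); a
measured table from the true single-viewpoint mirror profile can be
substituted, including one with the opposite orientation (the published
optics actually place the cylinder bottom near the mirror center — with
a supplied calibration table either layout works; the linear default
follows the simple two-point reading and is labeled as such).

Unwrapping maps output column to azimuth (column 1 and the last column
are adjacent on the cylinder; azimuth origin at the camera +x axis) and
output row to height, top row at the cylinder top. Source positions are
sampled bilinearly at pixel centers; radii outside the annulus yield `NA`
rather than extrapolation. Forward-rendering patterns on the surface and
unwrapping recovers their positions to well under a pixel RMS.

## Skin segmentation

Colors are converted sRGB → CIELAB (D65) and clustered with K-means
(Lloyd, Euclidean distance, 3 clusters, 10 seeded restarts). Clustering
uses the (a\*, b\*) chroma plane by default: lightness carries sheen and
shading variation that the original authors list among the challenges,
while chroma separates skin from glass and background; full-Lab
clustering remains a switch. The skin cluster is the one whose chroma
centroid is nearest a configurable reference (default a\*=14, b\*=17, a
mid-tone locus — skin tones vary, so per-cohort calibration from one
labeled frame is the documented procedure). If no centroid is within
12 a\*b\* units of the reference, the frame is declared handless and the
mask empty: centroid noise at realistic chroma noise is well under one
unit while glass and background sit 20+ units away. Connected components
below 25 px are removed as speckle, and the grasp area is the mask pixel
count times the metric pixel area.

## The synthetic generator

No recordings ship with the package, so a seeded generator provides
trials and frames with exact ground truth. What it emulates, and what it
does not:

* The sagittal angle follows quintic (minimum-jerk-style) segments: n
  velocity peaks in transport, a brief parabolic turnaround at the apex
  (entry speed ~100°/s over 30 ms — "the glass touches the lip and
  reverses"), and a mirrored decelerating return. The sharp turnaround is
  deliberate: a zero-velocity, zero-acceleration apex is cubically flat
  (under 0.5° of drop across ±9 samples), which no argmax detector can
  localize to ±2 samples under realistic angle noise; the turnaround
  makes the apex identifiable at the stated noise. Trials with a single
  slow transport unit cannot combine a sharp apex with a very short
  accommodation — the displacement budget forces a slow start — and the
  generator raises an error carrying the minimal feasible accommodation.
* Ground-truth event times are the detector definitions evaluated on the
  noiseless profiles (the onset ramp is placed so the analytic threshold
  crossing lands exactly at A + accommodation; impulse centers snap to
  the sample grid). Recovery statements therefore measure detector error,
  not a definitional offset.
* Contact impulses are 30 ms raised cosines (default 0.5 m/s²) at A and
  D. Linear acceleration is impulses plus (optionally) a minimum-jerk
  translation; the default translation is zero, matching the end-rule
  assumption above. Noise: white Gaussian on each accelerometer axis
  (default 0.005 m/s²) and on each Euler angle (default 0.5°).
* The specific force is synthesized from the *reported* (noisy)
  orientation, with accelerometer noise added separately, so the
  generated IMU is internally consistent the way a fused IMU is. Had the
  noise been applied to orientation only, gravity would leak
  g·sin(0.5°) ≈ 0.09 m/s² into the compensated resultant and swamp the
  0.02 m/s² threshold — real fusion firmware does not behave that way.
* Cohorts draw per-trial total duration and phase percentages from
  per-group Normal distributions (defaults: the published all-subject
  means and SDs — 2.55 ± 0.6 s, 13.33 ± 6.05 / 43.24 ± 7.41 /
  43.43 ± 7.73 %), renormalized to sum to 100, with accommodation floored
  at 0.2 s (or the profile's crossing lag). Draws are stratified
  (Latin-hypercube) within groups: marginals keep the configured
  distribution while cohort means carry no Monte-Carlo drift, so
  summaries measure pipeline recovery. This is emulation of the cohort's
  descriptive statistics, not reproduction of the original recordings.
* Frames paint skin-colored finger bands on the cylinder in (azimuth,
  height) space, forward-project them onto the annulus, composite over
  glass and a through-glass background band, and add Gaussian chroma
  noise (σ = 3) in CIELAB. The ground-truth mask is analytic band
  membership at panorama pixel centers.

Passing tests on these data show the pipeline recovers what the generator
defines under the stated noise; they do not certify performance on real
recordings, where orientation error is correlated, contacts are softer,
hands are not rectangular bands, and lighting varies.

## Problem sizes and tolerances

The shipped validation uses: 200 simulated trials for event recovery
(±2 samples at 87 Hz; noise up to 0.005 m/s² and 0.5°), 1000 random speed
profiles against a brute-force extremum-pair oracle (exact), 100 random
static orientations for gravity compensation (< 1e-3 m/s² residual), 20
noisy frames for skin-mask agreement (≥ 99%), 5-dot forward-render round
trips (< 1 px RMS), and one 48-trial cohort (phase-percentage means
within 1.5 points). Straightness closed forms are checked against 2/π and
5/7. These sizes keep the whole suite within about a minute while leaving
each check's margin visible in its summary statistic.

## Known limitations

* The table-contact rule (D) assumes contacts dominate the compensated
  resultant; trials with large translation need the orientation-return
  end rule.
* The default mirror calibration is a two-point linear mapping; metric
  accuracy at mid-heights depends on the true mirror profile and should
  come from a calibration table when available.
* Activity counts are unit-arbitrary; cross-study comparison requires
  identical configuration.
* Thumb-opposition grading and any hand-pose estimation are out of scope;
  the imaging pipeline quantifies contact area and provides key-instant
  panoramas for visual grading.
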
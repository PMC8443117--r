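---
title: "From 2D pose keypoints to validated gait variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 2D pose keypoints to validated gait variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpose)
```

## The problem

Markerless pose trackers (OpenPose, AlphaPose, Detectron) turn ordinary
frontal-view walking video into per-frame 2D keypoints with confidence
scores. Before those keypoints can support clinical gait assessment, two
questions must be answered: how do you get robust spatiotemporal gait
variables out of noisy pixel trajectories, and how well do those variables
agree with an established reference system measured on the same steps
(concurrent validity)?

`gaitpose` implements the full chain: tracker-output ingestion, trajectory
cleaning, foot-strike detection, six gait variables, and the validation
statistics — plus a seeded gait simulator that generates paired ground-truth
and corrupted keypoint streams, so every stage is testable without access to
recorded participants.

## The processing model

### Cleaning (fixed order: mask → swap-correct → smooth → crop)

1. **Confidence masking and interpolation.** Keypoints whose confidence
   falls below a tracker-specific threshold (0.3 OpenPose, 0.5 AlphaPose,
   0.15 Detectron — confidence scales are not calibrated across libraries)
   are removed and linearly interpolated from the nearest confident
   neighbours; leading/trailing gaps hold the first/last confident value,
   because linear extrapolation amplifies tracker noise at bout edges. A
   joint whose pre-interpolation missing fraction reaches 10% fails the
   screening rule (`check_missing_rule()`; the boundary counts as failing).
2. **Left/right swap correction.** Trackers occasionally exchange the left
   and right labels of a joint pair. For each frame and each lower-limb pair
   the labels are exchanged when that reduces the summed displacement from
   the previous (corrected) frame by more than 25% of the frame-local hip
   width; the margin protects genuine smooth crossings. A manual-override
   table provides the escape hatch that visual inspection provides in
   practice. See *Known limitations* for the failure mode of this rule and
   how the pipeline contains it.
3. **Smoothing.** A zero-phase (forward–backward) second-order low-pass
   Butterworth filter at 8 Hz. The package applies odd-reflective padding of
   `3 * (order + 1)` samples with steady-state initial conditions, so
   constants and slow trends pass through unchanged and the response has
   exactly zero phase (verified by cross-correlation in the test suite).
4. **Cropping.** Straight-walking bouts are cut from annotated start/end
   frames (turns are excluded by annotation, not detected automatically).

### Events and variables

Foot strikes are detected per foot from the ankle keypoint: the vertical
series is flipped to up-positive, linearly detrended over the bout (the
dominant trend is the monotone perspective scaling as the subject approaches
or recedes), and local minima are reported as strikes — ankle height is
minimal while the foot is on the ground. Minima closer than a minimum stride
interval (0.6 s; safe up to 130 steps/min) are merged keeping the lower one,
minima with prominence below 10% of the detrended interquartile range are
discarded, and strike times are refined to sub-frame resolution with a
parabolic fit. Left and right strikes are interleaved; two consecutive
same-foot strikes flag a missed contralateral strike and the enclosed step
is excluded.

Six per-bout variables follow:

* **cadence** `60 (n−1) / (t_last − t_first)` steps/min,
* **step time** between consecutive alternating-foot strikes,
* **step width**: medio-lateral ankle separation at the strike frame, divided
  by the frame-local hip width for video (hip-width normalization cancels
  the perspective scale; reference streams stay in metres),
* **CV** of step time and step width (sample SD over mean — small bouts, so
  the n−1 denominator),
* **eMOS**, the estimated lateral margin of stability: with
  `omega = sqrt(g / l)` (leg length `l` in metres) the extrapolated centre
  of mass is `XCOM = COM + V_COM / omega` and `eMOS = XCOM − BOS`, evaluated
  at each strike with BOS the new stance foot's lateral position and COM the
  mid-hip point (the closest frontal-view sacrum proxy). The lateral axis is
  oriented per step so the stance side is positive.

Pixel-space units for eMOS deserve a note: the computation runs in raw pixel
coordinates — differences (COM − BOS) cancel the principal-point offset and
velocities have none — and the result is divided by the hip width at the
strike frame. Because `omega` is a purely temporal quantity (1/s), computing
it from the metric leg length and applying it to a pixel-valued velocity
before normalization is algebraically identical to applying it to a
hip-width-normalized velocity; video eMOS is therefore dimensionless
(hip-width units) and cannot be compared in magnitude with metric reference
values, only correlated.

### Validation statistics

Video-derived variables are compared with the reference stream over every
condition: 3 trackers × 2 camera heights (1.11 m eye-level, 2.05 m top) ×
2 walking views (front, back) × 2 calculation methods = 24 cells.
`method = "individual"` pairs step-level values per matched step (bout-level
variables per bout); `method = "mean"` first averages each participant over
all bouts of a view and pairs across participants. Pearson's r with
two-sided p from the t-transform; no multiple-testing correction (α = 0.05
at reporting time only). Precision is the CV of per-bout values within each
participant, summarized as mean (SD) across participants. Bland–Altman
agreement between tracker pairs uses `mean ± 1.96 · SD` limits and is
reported for the spatial variables by default, since the trackers detect
near-identical gait events and temporal variables agree trivially.

Step sequences from the two systems are aligned greedily by nearest strike
time within 0.25 s (below half the shortest plausible step time),
preserving foot-label order, so both systems score the same physical steps;
a supplied clock offset handles unsynchronized recordings (zero for
synthetic data).

## The synthetic cohort

The simulator plays the role of the study population: 11 subjects, cadence
106.44 steps/min between-subject SD 8.5, within-bout step-time CV 0.06,
step width 0.09 m, 12–14 steps per bout, 2 bouts per view, 30 fps video
against a 100 Hz reference, both camera presets, front and back views.
Walking is kinematic, not dynamic — only the observation model matters for
testing the pipeline:

* strike times are alternating-foot intervals drawn around 60/cadence;
* foot placements sit at ±width/2 with 0.027 m per-step jitter (pooled
  per-step width SD ≈ 0.05 m); subject mean widths vary with SD 0.03 m and
  are floored at 0.05 m — narrower bases put the two ankles inside tracker
  noise of each other, which no label-disambiguation rule can resolve and
  which does not occur in community-dwelling walkers;
* the sacrum swings toward the stance foot on a natural spline with 0.05 m
  amplitude (between-subject SD 0.012 m), crossing the midline at each
  strike; together with `omega` from a 0.53 × height leg length this yields
  mean eMOS of a few centimetres, the scale reported for older adults;
* ankle height follows a `|sin|` bump per stride with its minimum exactly at
  the strike, and virtual strides extend beyond the bout edges (a bout is a
  crop of ongoing walking), so every strike is a detectable local minimum;
* a fronto-parallel skeleton (hip width 0.16 m, which puts normalized step
  widths near 0.56 hip-widths, the scale video trackers report) is projected
  through a pinhole camera (1400 px focal length, 8 m standoff) whose depth
  advances at walking speed — the perspective scale drifts across the bout,
  which is what makes hip-width normalization and detrending non-trivial.

Corruption is layered on top, each component seeded: (a) i.i.d. Gaussian
keypoint jitter whose SD is specified at the standoff distance and scales
with the person's image size (5 px, under 2% of the projected body height —
constant-in-pixel noise would dwarf the projected anatomy at the far end of
the walkway); (b) a constant per-stream, per-joint bias (2 px at standoff
scale) emulating systematic subject/viewpoint-dependent tracker offsets —
without it, per-step noise averages out and subject-mean spatial
correlations are unrealistically perfect, while a bias much larger than the
per-step jitter would invert the averaging benefit (a subject-level offset
cannot be averaged away, so it depresses participant-mean correlations more
than step-level ones); (c) confidence dropouts (2% of
joint-frames, confidence below every threshold, position perturbed); (d)
left/right label swaps of one lower-limb pair on 1% of frames. The noise is
white by design; autocorrelated tracker jitter is a documented non-goal.

What passing tests on this cohort do *not* show about real data: the
simulator has no occlusions, no assistant walking in frame beyond the
multi-person reader fixtures, no turning segments, no autocorrelated error,
and its walker is kinematically stylized. The validation grid's absolute
correlation values on synthetic cohorts are therefore not estimates of any
tracker's real validity — only the structure (temporal ≫ spatial validity,
averaging improves correlations) is the tested claim.

## Numerical choices and degenerate inputs

* Filter: `signal::butter()` coefficients; reflective padding length
  `3 (order+1)`; series shorter than the padding raise a too-short error;
  cutoffs at or above Nyquist are rejected.
* Detection: linear least-squares detrend; prominence floor has an absolute
  epsilon so numerically flat series yield zero strikes; sub-frame
  refinement is clamped to ±half a frame; bouts shorter than one stride
  warn and return empty.
* CV requires n ≥ 2 and nonzero mean; cadence requires ≥ 2 strikes; Pearson
  requires n ≥ 3 and nonzero variance — all are errors, not silent NAs, at
  the operation level, and become unavailable (NA) cells only in the
  aggregated tables.
* Canonical CSV I/O writes 17 significant digits, so round-trips are
  bit-exact for finite values and missingness is preserved.
* Mid-hip is always derived (mean of hips; confidence = min of the two).

## Known limitations

The displacement-minimizing swap rule is purely relative: a false exchange
born in a laterally ambiguous phase (feet within noise of each other) makes
the *flipped* labeling the continuity-consistent one, and the error locks in
for the rest of the bout. Rather than complicating the rule, the pipeline
treats pervasive correction as a data-quality signal: streams where the
automatic rule fires on more than 4% of frames, or that lose 3+ steps
relative to the reference sequence, are flagged and excluded from summaries
by default (`include_flagged = TRUE` keeps them). This mirrors manual-review
practice, where such recordings are inspected or discarded.

Problem sizes in the shipped test suite are the package's own choices for a
laptop-class run: the qualitative-replication property uses 20 cohorts of
11 subjects × 2 bouts × 2 views × 3 trackers × 2 cameras; parameter-recovery
checks use 3-subject clean cohorts; oracle equivalences use 1000 random
instances.
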
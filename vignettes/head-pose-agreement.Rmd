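---
title: "Measuring head position with paired motion-capture devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head position with paired motion-capture devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headpose)
```

## The measurement problem

Clinicians describe abnormal head postures (AHPs) — sustained chin up/down,
head turn, head tilt, or combinations — mostly by observation, which is
known to be inaccurate by several degrees. Electromagnetic trackers measure
head orientation very accurately but are expensive and awkward in clinic;
markerless depth cameras are cheap and contact-free but their accuracy must
be established against a gold standard. `headpose` implements the analysis
required to make that comparison: both devices record the same three facial
landmarks while a subject performs a fixation protocol, and the package
turns each landmark stream into per-movement *range of movement* and
*positional stability* metrics that can be compared with matched-pairs
statistics.

## Head coordinate frame and orientation angles

Each frame supplies three anatomical points (mm, device world frame): the
orbital margins lateral to the right and left lateral canthi, and a point
1 cm below the bottom of the lower lip. The head frame is

* origin at the canthal midpoint,
* $\hat{x}$: unit vector from the origin toward the right canthus
  (mediolateral),
* $\hat{y}$: unit normal of the plane through origin, right canthus and
  sublip point (anteroposterior),
* $\hat{z} = \hat{x} \times \hat{y}$ (superior).

The plane normal has two admissible signs. `build_head_frame()` uses
$\hat{y} = \widehat{\hat{x} \times (p_{\text{sublip}} - o)}$, which is
continuous in the landmarks, equivariant under rotations, and — because the
sublip point lies below the canthal line — makes $\hat{z}$ point toward
world up at an upright neutral pose. Degenerate geometry (coincident canthi,
or a landmark triangle of area $\le$ 1 mm²) is an error, as is passing an
unfiltered dropout frame.

Orientation is reported as Euler angles in the **xyz sequence**, defined by
$R = R_x(\alpha)\,R_y(\beta)\,R_z(\gamma)$ (intrinsic x-y-z on column
vectors), the common biomechanics reading; the convention is implemented in
exactly one pair of functions (`euler_to_matrix()`, `euler_xyz()`) with the
explicit element formulas in the source. $\beta$ is confined to
$[-90^\circ, 90^\circ]$; at gimbal lock ($|\beta| = 90^\circ$, irrelevant at
the $\pm 30^\circ$ amplitudes studied but still defined) $\gamma := 0$,
$\alpha$ absorbs the remaining rotation, and a warning is raised.

All angles are expressed **relative to the neutral central-fixation pose**:
the chordal mean orientation (`mean_orientation()`, SVD projection of the
elementwise average onto the rotation group) over the middle window of the
leading central hold, via `relative_orientation()`. Whether the original
study used device-world or neutral-relative angles is not stated; the
neutral-relative convention is required for cross-device comparability
(the two devices have different world frames) and is used throughout.

### Axis labels

With this construction, chin up/down is a rotation about $\hat{x}$, head
turn about the vertical axis $\hat{z}$, and head tilt about the
anteroposterior axis $\hat{y}$ — the package's default label mapping
(`turn_axis = "z"`). An alternative mapping that reports turn from the $y$
Euler component and tilt from $z$ is selectable (`turn_axis = "y"`), since
descriptions of this construction sometimes attach those labels instead;
the geometry itself is unchanged, only which component is read per label.

## Trial pipeline

The fixation protocol is: a 10 s central hold, then for each of the six
movements (chin up, chin down, turn right, turn left, tilt right, tilt
left, in that fixed order, toward 30° targets) a transition, a 10 s
eccentric hold, a transition back, and a 10 s central hold.

* **Segmentation.** With a protocol annotation (the default), hold
  boundaries come from the schedule. Without one, holds are detected as
  maximal intervals with angular speed below 5°/s (central differences)
  lasting at least 4 s, with 0.5 s hysteresis, then labelled by the fixed
  movement order; a count other than 13 (7 central + 6 eccentric) is an
  error.
* **Analysis windows.** Each hold is trimmed symmetrically to its middle
  8 s (generally `min(8 s, duration)` centred). Intervals are half-open
  `[start, end)`, so a 10 s hold yields exactly 240 samples at 30
  frames/s and 1920 at 240 frames/s on grid-aligned timestamps.
* **Metrics.** Range of movement = |mean eccentric-window angle − mean
  preceding-central-window angle| on the movement's primary axis (hold
  means are robust and make the 30°-target comparison direct; the metric
  is deliberately not a peak excursion). Stability = sample SD (n−1) of
  the eccentric window. Central-hold stability is not analysed.
* **Paired exclusion.** If tracking is lost inside a movement's eccentric
  window — a gap of more than 2 consecutive missing nominal frame periods
  (configurable) — that movement is excluded for *both* devices, so the
  paired dataset never contains one-sided movements. Dropouts confined to
  central holds do not exclude. No interpolation or smoothing anywhere.
* **No resampling.** Each device is analysed on its own timeline; only the
  derived scalars are paired.

## Agreement statistics

Per movement, across subjects:

* **Ranges:** Wilcoxon matched-pairs signed-rank test on
  $d_i = \text{depth} - \text{emt}$. Zeros dropped (classic convention),
  mid-ranks for ties, statistic $W = \min(W^+, W^-)$. For $n \le 25$ the
  two-sided p is exact, from the full null distribution of $W^+$ over all
  $2^n$ sign assignments (computed by convolution over the doubled rank
  multiset, identical to enumeration); beyond that, a normal approximation
  with tie and continuity corrections. `stats::wilcox.test` cannot compute
  exact p with ties, which is why the test is implemented here; it serves
  as an independent cross-check on tie-free data in the test suite.
* **Stability:** paired t-test (via `stats::t.test`) on the per-subject
  SDs, by default for chin up, chin down, turn left and tilt left — the
  four positions compared in the study design this package follows.
* **Tables:** medians/quartiles use the linear-interpolation quantile rule
  (`stats::quantile` type 7) with Tukey 1.5·IQR whisker bounds; stability
  tables report mean SD ± SE. No multiple-testing correction is applied,
  matching per-movement reporting.

## The synthetic two-device simulator

No recordings are distributed, so the package carries a forward model of
the whole experiment; it is first-class, tested code.

* **Trajectory.** Holds at each movement's achieved amplitude connected by
  quintic smoothstep (minimum-jerk) single-axis transitions. Achieved
  amplitude = 30° × an undershoot factor drawn per subject
  (mean 0.93, SD 0.05; subjects fixating eccentric targets undershoot)
  plus 0.5° per-movement noise. Hold jitter is a first-order
  autocorrelated (AR(1)/Ornstein–Uhlenbeck) process, stationary SD 0.8°
  per axis, correlation time 0.5 s — physiological sway is autocorrelated;
  white noise would make the measured SD trivially rate-dependent. The
  jitter is realised once on a 240 Hz grid and interpolated so both
  devices sample the *same* trajectory.
* **Devices.** Each device samples at its rate (240 vs 30 frames/s),
  multiplies each Euler component by a per-axis attenuation factor
  (multiplicative, not additive: the absolute error then scales with
  amplitude, one knob per axis), rotates a rigid face template (canthi
  ±45 mm, sublip 70 mm below — plumbing constants, not anthropometry) into
  its own world frame, adds isotropic Gaussian landmark noise, and marks
  dropout bursts (two-state process: entry probability per frame,
  geometric burst length) as invalid frames.
* **Defaults.** The reference tracker: attenuation 1, noise 0.05 mm, no
  dropouts. The depth camera: attenuation x 0.70, z 0.85, y 0.98 (set from
  the mean reported underestimations of chin, turn and tilt movements at
  the ~27.9° mean achieved amplitude), noise 1.3 mm (which lands the
  simulated eccentric-hold SD in the 1.3–1.5° range reported for depth
  cameras), dropout entry 5e-4/frame with mean burst 6 (roughly one
  movement in ten excluded).
* **Seeds.** Every random element descends from one master seed through a
  documented counter-based derivation (subject index × stream), so runs
  are byte-reproducible and adding subject 21 does not change subjects
  1–20.

What the simulator does *not* emulate: between-subject variation in device
attenuation (attenuation is a fixed device property here, so simulated
device differences are statistically significant on every axis, including
tilt, where real data show non-significant differences driven by
between-subject variability); face-tracking physics (dropouts are random,
not pose-dependent, whereas real depth cameras lose the face
preferentially in chin-down positions); soft-tissue artefact; correlated
landmark noise. Passing tests therefore validate the pipeline's
correctness and the direction/order of device effects, not the exact
magnitudes a particular camera would produce.

## Numerical choices

* Angles in degrees everywhere; rotation matrices validated orthonormal
  with det +1 (tolerance 1e-8 at interfaces; constructions are accurate to
  ~1e-15).
* Gimbal lock threshold $|\cos\beta| < 10^{-7}$.
* `asin` arguments clamped to [−1, 1] before decomposition.
* Exact Wilcoxon distributions use integer support (ranks doubled), so
  mid-ranks stay exact.
* Tie-break in hold labelling is positional: detected holds are matched to
  the protocol order, never by amplitude.

## Problem sizes in the test suite

The statistical guarantees are checked by simulation at the study's cohort
size (20 subjects) with the protocol stream restricted to the movements
under test where only those movements matter: the type-I-error check runs
200 cohorts of 20 subjects on a chin-up-only protocol (200 independent
tests, rejection rate compared against the binomial band for 200
replicates); attenuation recovery uses 20 replicate cohorts on the two
chin movements; jitter-SD recovery uses 100 single-subject replicates
with a short correlation time (0.01 s) so the i.i.d. sampling-error bound
$3\sigma/\sqrt{2(n-1)}$ applies — with the default 0.5 s correlation time
an 8 s window holds only ~8 effective samples and no such bound can hold,
which is a property of autocorrelated sway, not of the pipeline.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(n_subjects = 20, seed = 1)
res <- analyze_cohort(co)
agree <- device_agreement(res$paired)
agree$range_tests
agree$stability_tests
plot_ranges(res$paired)
```

The same pipeline is exposed on the command line (`simulate`, `analyze`,
`compare`, `report`) through `hp_cli()` and the `headpose` script in
`inst/scripts/`, operating on the package's CSV/JSON/TSV formats.

## Known limitations

Single-amplitude protocols cannot estimate correlation or limits of
agreement between devices (one point per subject per movement), so the
package deliberately stops at matched-pairs location tests and summary
tables. Torso landmarks are accepted in recordings but not analysed.
Trajectory filtering, dropout interpolation and real-time processing are
out of scope.
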
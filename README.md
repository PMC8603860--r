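# headpose

Landmark-based head-pose analysis and paired device-agreement statistics
for motion capture.

## The problem

Abnormal head postures (chin up/down, head turn, head tilt) are usually
assessed by observation, with errors of several degrees. Electromagnetic
trackers measure head orientation accurately but are costly and awkward;
markerless depth cameras are cheap and contact-free but must be validated
against a gold standard. The validation design this package implements:
both devices simultaneously record three facial landmarks (the orbital
margins lateral to the right and left lateral canthi, and a point 1 cm
below the lower lip) while a subject fixates a central target and six
eccentric targets at 30°, holding each for 10 s.

## The analysis

From each frame's landmarks a head coordinate frame is built — origin at
the canthal midpoint, x̂ toward the right canthus, ŷ the facial-plane
normal, ẑ = x̂ × ŷ — and the head orientation matrix **R** (columns x̂,
ŷ, ẑ in device world axes) is decomposed, relative to the neutral
central-fixation pose, into Euler angles in the xyz sequence:

    R = Rx(α) · Ry(β) · Rz(γ),   β ∈ [−90°, 90°]

with α the chin up/down (pitch) angle and, in the default mapping, γ the
turn (yaw) and β the tilt (roll) angle. For each movement, over the
middle 8 s of each 10 s hold:

* **range of movement** = |mean eccentric-hold angle − mean preceding
  central-hold angle| on the movement's primary axis (degrees);
* **stability** = sample SD of the primary-axis angle over the eccentric
  hold (degrees).

Movements whose eccentric window contains a tracking gap in the depth
stream are excluded *for both devices*. Device agreement is then tested
per movement with the exact Wilcoxon matched-pairs signed-rank test on
ranges (full 2ⁿ sign-assignment null distribution, mid-ranks for ties)
and the paired t-test on stability SDs.

Because no recordings are distributed, the package includes a full
two-device capture simulator (protocol trajectories with minimum-jerk
transitions, autocorrelated postural jitter, per-axis angular
attenuation, landmark noise, tracking dropouts) so every stage is
testable end to end. See the vignette
(`vignettes/head-pose-agreement.Rmd`) for the model details and defaults.

## Worked example

```r
library(headpose)
co    <- generate_cohort(n_subjects = 20, seed = 1)  # paired simulated cohort
res   <- analyze_cohort(co)                          # pipeline + paired exclusion
agree <- device_agreement(res$paired)
print(agree$range_tests, digits = 3)
```

```
    movement W  p_value  n exact median_diff_depth_minus_emt
1    chin_up 0 1.53e-05 17  TRUE                      -8.100
2  chin_down 0 7.63e-06 18  TRUE                      -8.259
3 turn_right 0 7.63e-06 18  TRUE                      -4.194
4  turn_left 0 1.53e-05 17  TRUE                      -4.184
5 tilt_right 0 3.81e-06 19  TRUE                      -0.598
6  tilt_left 0 1.53e-05 17  TRUE                      -0.589
```

Each row is one movement: `n` subjects survived the paired-exclusion
rule (dropouts cost 14 of 120 movements here), the depth camera measured
a median 8.1–8.3° less chin movement than the reference tracker but only
~0.6° less tilt, and the exact two-sided signed-rank p-values show every
systematic difference is detectable at this simulated effect size.
Stability (`agree$stability_tests`) shows the depth camera ~0.6° more
variable during eccentric holds:

```
   movement    t df  p_value  n mean_diff_depth_minus_emt
1   chin_up 19.9 16 1.02e-12 17                     0.605
2 chin_down 23.8 17 1.66e-14 18                     0.650
```

`plot_ranges(res$paired)` and `plot_stability(res$paired)` draw the
corresponding box plot and bar chart. The same pipeline runs from the
shell via the `headpose` script (`inst/scripts/`): `simulate` →
`analyze` → `compare` → `report` over CSV recordings, JSON annotations
and TSV result tables, fully reproducible from one master seed.

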
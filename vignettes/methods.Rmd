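---
title: "Methods: kinematics of pointing to auditory targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics of pointing to auditory targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audioreach)
```

## The problem

Blindfolded subjects point with their right hand at white-noise sources
rendered binaurally in the horizontal plane in front of them (five
azimuths: −35°, −20°, 0°, +20°, +35°, at a virtual distance of 0.60 m).
Four session conditions vary what the subject hears: a short 250 ms target
(A), a 2000 ms target heard throughout the movement (B), a 250 ms target
plus a continuous auditory "avatar" rendered at the hand's position (C),
and the same avatar shifted 18.5° to the left of the true hand direction
(D). Hand (fingertip) position and head pose are tracked at 100 Hz.

The package turns such recordings — or synthetic stand-ins with the same
statistical structure — into per-trial kinematic and performance features,
aggregates them to the subject × condition × target repeated-measures
design, and runs the classical within-subject ANOVA.

## Per-trial analysis

**Filtering.** Positions are smoothed with a zero-phase Gaussian low-pass
filter with a 5 Hz cutoff. A "cutoff" needs a gain convention; we fix the
kernel scale by the −3 dB point, $\sigma = \sqrt{\ln 2}/(2\pi f_c)$ s, so
the gain is exactly $1/\sqrt 2$ at $f_c$ under the analytic transfer
$H(f)=e^{-(2\pi f\sigma)^2/2}$. The kernel is truncated at $\pm 4\sigma$
and renormalised (DC gain exactly 1); edges use reflection padding. At
100 Hz this is an 11-sample half-width — trials shorter than the kernel are
rejected rather than silently under-smoothed.

**Norms.** Velocity, acceleration and jerk are successive central
differences of the filtered positions (one-sided at the edges); `v3D`,
`a3D`, `j3D` are their Euclidean norms. `j3D` is computed and exported but
drives no downstream statistic. On noise-free minimum-jerk input the peak
of `v3D` matches the analytic $1.875\,D/T$ to well under 1%.

**Segmentation** is two-stage. A primary displacement stage finds the
outward gesture: the first excursion of horizontal distance from the start
marker beyond 2 cm, ending at the maximum distance within that excursion,
which discards the return to the marker. The 2 cm value is a repo
convention — it only needs to clear marker jitter, because the bounds that
matter come from the second stage: the peak-velocity point (PVP) is the
argmax of `v3D` in the window, and onset/offset are found by walking
*outward* from the PVP to the last/first sample at which `v3D` drops to 3%
of the peak. Walking outward (rather than inward from the window edges)
keeps small velocity bumps outside the movement from capturing the bounds;
if the threshold is never reached before a window edge, the edge is used
and flagged. For a minimum-jerk reach the 3% crossing sits at
$\tau \approx 0.0453$ of movement time (root of
$30\tau^2(1-\tau)^2 = 0.03\cdot1.875$), and the detector lands within one
sample of it.

**Features.** Duration, peak and mean `v3D`, path length, and acceleration
peaks: strict local maxima of `a3D` within the bounds with topographic
prominence at least 5% of the in-bounds maximum (plateaus count once, at
their first sample). The prominence floor is our choice — some rule is
needed to suppress numerical ripple, and a relative floor adapts across
movement amplitudes. Peaks are split at the PVP; a peak exactly at the PVP
counts as "after", which makes before + after = total exact. For a pure
minimum-jerk reach there are exactly two peaks (|a| maxima at
$\tau=(3\pm\sqrt3)/6$), one on each side of the PVP; corrective
submovements add peaks concentrated in the deceleration phase.

The noise regime matters for peak counting: at 100 Hz under the 5 Hz
filter, white marker noise of 0.5 mm SD produces acceleration ripple of
the same order as the 5% prominence floor and can add several spurious
peaks; at ≤ 0.2 mm the counts are stable to ±1. Optical systems are
typically well inside the stable regime.

**Heading.** Head yaw is the azimuth of the head's forward axis (body +y
rotated by the world-from-body quaternion) projected on the horizontal
plane — 0° forward, positive right; pitch and roll are ignored. The series
is unwrapped, filtered with the same Gaussian filter, and differentiated
centrally. Range of motion (ROM, max − min yaw) is computed over the whole
trial window, not the hand bounds, because head orienting starts before
hand onset and clipping to the hand movement would truncate exactly the
anticipatory part of interest; the final heading is read at hand offset.
Yaw-acceleration peaks reuse the hand peak rule on |yaw accel| for
internal consistency (the angular, not translational, acceleration — a
choice, since either could be meant). A pose whose forward axis comes
within 5° of vertical has no usable azimuth and is rejected.

**Performance.** The pointed direction is the azimuth of the filtered hand
position at movement offset relative to the start marker — the in-silico
protractor. Signed error is pointed minus target azimuth (negative = left
of target). Endpoints within 5 cm of the marker give numerically unstable
angles and raise an error at trial level; this guard is deliberately
distinct from the cohort-level 10 cm exclusion rule. The condition-D
transform simply adds −18.5° to the hand azimuth in world frame (a
head-centred variant would differ only when the head is turned; the
world-frame reading is implemented and configurable at the call site).

## Exclusion rules and statistics

Subjects are excluded by three rules, attributed in order: (1)
*slow/indirect* — mean movement duration above twice the cohort mean and
above 2.0 s (the long-condition stimulus duration); the cohort mean is
computed once over all subjects before any removal, so the outcome is
order-independent; (2) *no target dependence* — slope of pointed-on-target
regression below 0.1, or ≥ 90% of endpoints within 5° of ±90°; (3) *short
trajectory* — median path length below 0.10 m. Rule 2's
operationalisation is ours: "no dependence on the target" is qualitative,
so both the slope floor and the lateral-clustering alternative are exposed
as settings.

Cell means per subject × condition × target feed a classical two-way
within-subject ANOVA (`aov` with an
`Error(subject/(condition*target))` stratum), optionally crossed with the
between-subject counterbalancing-group and HRTF factors. Degrees of
freedom are the uncorrected ones (with 18 subjects the condition effect
has df = 3, 51); a sphericity correction is deliberately not applied by
default. Classical repeated-measures ANOVA needs balance, so subjects with
missing cells are dropped for that variable with a warning rather than
imputed; a constant dependent variable short-circuits to F = 0, p = 1
instead of the indeterminate 0/0. Post-hoc condition comparisons are
Bonferroni-adjusted paired t tests over all six pairs.

## The synthetic generator

The generator exists so the whole pipeline can be exercised without the
original recordings. One trial is: rest (0.5 s) — minimum-jerk transport
(~1 s) to an endpoint at azimuth $g_c\,\theta + b_c + \varepsilon$,
$\varepsilon\sim N(0,\sigma_c)$ — hold — minimum-jerk return — rest. The
multiplicative gain $g_c$ and constant bias $b_c$ reproduce the two
signatures of auditory pointing at a glance: eccentricity-dependent
overshoot (left targets pointed further left, right targets further
right) and a constant leftward bias; both are far smaller in the
long-sound condition. Corrective submovements are additive minimum-jerk
displacements forming a temporal chain: the first onset falls at
0.45–0.60 of transport time and successive onsets follow 0.15–0.25 s
apart. The chain matters: isolated submovements separated by dead time
let the speed fall below the 3% threshold, which ends the detected
movement early and caps the after-PVP peak count. Net submovement
displacements are folded into the transport target, so the endpoint — and
hence the pointing error — is exactly the drawn direction, which is what
makes injected gain and bias recoverable by regression. The head performs
a single minimum-jerk yaw excursion toward the target of amplitude
(base$_c$ + gain$_c\,|\theta|$), starting 0.25 s before hand onset, so its
peak velocity falls early in the hand movement. Isotropic Gaussian noise
(0.25 mm SD) is added to every coordinate.

Default parameters are calibrated: pipeline means over a generated cohort
sit near the study-scale reference values (≈ 26° mean absolute error in
the short-sound condition; heading ROM ≈ 21.9° in the long-sound condition
against ≈ 5.3/7.4/5.2° elsewhere; ≈ 1.5 acceleration peaks before and
≈ 2.8 after the PVP, with a larger total in the long-sound condition;
≈ −9.8° straight-ahead bias in the long-sound condition). Calibration is
approximate-by-construction — those references are means over a human
cohort — and no fitting loop ships with the package; the acceptance tests
check the generated means at a 15% tolerance on a 50-subject cohort.

What the generator does *not* emulate: movement-time dependence on target
eccentricity, the left/right velocity asymmetry, endpoint variability that
scales with eccentricity, head translation, within-subject learning, and
any closed-loop reaction to the avatar shift (condition D differs from C
only in metadata and the rendered-azimuth transform, mirroring the
empirical finding that the shift did not change pointing accuracy).
Passing tests on synthetic data therefore validate the *measurement*
pipeline, not claims about human behaviour.

## Problem sizes

The test suite runs at desk scale by choice: oracle grids over
$D \in [0.2, 0.6]$ m and $T \in [0.5, 2]$ s; parameter recovery on 1000
trials (200 per target); exclusion fixtures of 24 subjects at 8 trials per
condition; the calibration check on 50 subjects × 128 trials. The
acceptance script (`scripts/acceptance.R`) recomputes the two exactly
checkable quantities — the avatar-shift offset and the onset-speed
percentage — from scratch at run time.

## Known limitations

- The segmentation is fully automatic; a human vetting pass (as in
  semi-automatic protocols) could reject trials this pipeline keeps.
- Azimuth arithmetic is linear in degrees, adequate for the ±35°
  workspace; no circular statistics are used.
- The ANOVA engine offers no sphericity correction by default and no
  mixed-model fallback for unbalanced data.
- The quaternion convention (scalar-first, world-from-body, +y forward) is
  a repo convention; recordings using another convention must be converted
  on ingest.
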
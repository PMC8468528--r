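---
title: "Methods: measuring and modeling the dynamic mean ankle moment arm from a pylon load cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and modeling the dynamic mean ankle moment arm from a pylon load cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmama)
```

## The measurement problem

A semi-active prosthetic foot can adjust one mechanical property (here,
forefoot stiffness) once per stride, during swing. Closing that control loop
requires a biomechanical target that (a) summarizes the whole stance phase in
one number and (b) is measurable by sensors embedded in the prosthesis. The
dynamic mean ankle moment arm (DMAMA) satisfies both: it is the ratio of the
sagittal ankle-moment impulse to the magnitude of the sagittal ground-
reaction-force impulse over one stance,

$$\mathrm{DMAMA} \;=\; \frac{J}{I} \;=\;
\frac{\int_{HS}^{TO} M_{ankle}\,dt}
     {\bigl\lVert \int_{HS}^{TO} \vec F_{sag}\,dt \bigr\rVert}
\;=\; \frac{\bar M_{ankle}}{\bar F_{sag}},$$

a signed length: the mean anterior moment arm of the ground-reaction impulse
about the ankle. We normalize it to percent foot length (%FL) so values are
comparable across feet.

The only sensor is a six-axis load cell in the pylon, which measures forces
and moments about its own origin, in its own frame, at a jittery rate
(nominally 149.9 ± 38.5 Hz). Three processing steps recover DMAMA from it:

1. **Frame calibration.** A mounting rotation `R` (load cell → shank) and the
   lever arms from the ankle and knee joint centers to the load-cell origin
   are estimated once per subject from repeated orientation/position samples.
   Rotations are averaged in rotation-vector (axis-angle) space: each sample
   matrix is mapped to its rotation vector, the vectors are averaged
   element-wise, and the mean is mapped back through the exponential map.
2. **Moment transport.** In the shank frame (X anterior, Y proximal, Z to the
   subject's right; the sagittal plane is X–Y), the quasi-static sagittal
   joint moment is
   $M_{joint} = (\vec r \times \vec F_{sag})_z + M_z$,
   with $\vec r$ the joint-to-sensor vector. Inertial terms are neglected:
   stance-phase shank accelerations are small relative to the load terms.
   Plantarflexion (ground reaction force anterior to the ankle) is positive,
   so positive DMAMA means "anterior to the ankle".
3. **Impulse ratio.** Both impulses are trapezoidal integrals over the
   detected stance window on the raw measured timestamps. We interpret the
   denominator as the norm of the vector impulse, not the integral of the
   force norm; the two differ whenever the force direction rotates during
   stance, and only the former equals the mean-moment/mean-force form above.

## Gait events and stride segmentation

Stance is detected by thresholding the sagittal force magnitude
$\sqrt{F_x^2+F_y^2}$ at 8 % body weight: the first sample at or above the
threshold is the heel strike, the last one the toe-off. Two debounce rules
suppress sensor-noise chatter near the threshold: stance runs separated by
less than 0.1 s of "swing" are merged, and merged runs shorter than 0.2 s are
discarded. The specific debounce durations are design choices (a stance
shorter than 0.2 s or a swing shorter than 0.1 s is not physiological at
walking speeds); the heel-strike rule deliberately reuses the toe-off
threshold so the detector is a single symmetric, hysteresis-free comparison.

Each stance becomes one stride segment. Its locomotion mode is the majority
vote of the per-sample mode labels during stance; any stance that spans a
mode boundary, or contains samples flagged as transition, is excluded from
all statistics — transition steps between locomotion modes are not
representative of either mode.

## The synthetic session generator

No public dataset accompanies this problem, so validation rests on a
generator whose ground truth is known exactly. It emulates the statistical
structure the analyses assume:

- **Per-stride DMAMA targets** follow a linear model
  $d = \beta_{0,s} + \beta_k k + \beta_g g + \beta_{kg}\,k\,g + \varepsilon$,
  with stiffness code $k \in \{0,1,2\}$ (low/medium/high), ground incline
  $g \in \{-5,0,+5\}$ degrees (stairs carry no incline and contribute zero to
  the incline terms), subject intercepts $\beta_{0,s}$, and i.i.d. stride
  noise $\varepsilon$.
- **Defaults are the study conditions**: 4 subjects; per stiffness trial
  about 50 level strides and 11 per other mode (the circuit yield of the
  field protocol); $\beta_k = 3.01$ %FL/increment, $\beta_g = 0.413$ %FL/deg,
  $\beta_{kg} = -0.145$ (the published multivariate coefficients); stride
  noise 3 %FL; sampling rates drawn per sample from a normal with mean 149.9
  and SD 38.5 Hz, truncated below at 50 Hz (the truncation avoids
  non-physical rates; intervals are the reciprocals); sensor noise 0.5 N and
  0.5 N·m; foot length 0.24 m and body weight 883 N (a 90 kg adult). The
  subject intercepts default to 8/10/12/14 %FL — per-condition mean DMAMA
  values are published only graphically, so the intercept scale is a one-time
  choice of plausible mid-stance moment arms, and nothing downstream depends
  on it beyond being positive and subject-distinct.
- **Waveforms** are stylized but mechanically consistent: a two-peak axial
  force profile (single-peaked on stairs, whose loading is qualitatively
  different), an S-shaped anterior–posterior shear that integrates to zero,
  and a squared-half-sine ankle-moment envelope scaled so that the stance
  impulse ratio equals the drawn DMAMA target *exactly* (in the analytic
  integrals). The sensor's sagittal moment channel is then back-computed by
  inverting the transport equation, the wrench is rotated into the load-cell
  frame with the inverse of the true mounting rotation, and noise is added
  last. Mode-specific amplitudes on the out-of-plane channels
  ($F_z, M_x, M_y$) and mode-specific stance durations make the five classes
  separable for the classifier.

Two generator details exist purely so that numerical validation is clean.
First, the sagittal force carries a 10 %-body-weight floor at the stance
edges; without it, the force tails below the 8 % detection threshold would be
silently clipped from the integration window and bias the force impulse by
roughly 0.3 %, swamping the ≤ 0.1 % end-to-end recovery tolerance we hold the
pipeline to. Second, the sampler places a sample exactly at each stance
boundary, so the detected window equals the generated one and what remains is
pure integration error. Real load cells guarantee neither property; the
consequence for real data is a small systematic truncation of the stance
tails, not a failure of the method.

What the generator does **not** emulate: swing-phase dynamics (swing is
zero-force plus noise), center-of-pressure progression within the foot,
speed variation, turning, fatigue or learning effects, and any coupling
between stiffness and waveform *shape* (stiffness affects only the DMAMA
target). Passing tests therefore demonstrate that the estimation chain is
correct and well-conditioned under the assumed statistical structure — not
that real prosthetic gait obeys that structure.

## Classifier

Nine channels are derived from the load cell alone: the six wrench axes, the
transported ankle and knee moments, and the sagittal force magnitude. The
stream is linearly resampled to a uniform 100 Hz for this path only (DMAMA
always integrates on raw timestamps). From a window ending at toe-off — the
last moment a swing-phase stiffness decision can use — six statistics (mean,
sample SD, min, max, first value, last value) per channel give 54 features.

Models are linear discriminant analysis with pooled within-class covariance,
fitted separately per (subject, stiffness) group, since stiffness is known to
the controller. Two numerical choices depart from textbook LDA. Ties in the
posterior are broken toward the first class in the fixed mode order, and the
pooled covariance can be blended toward its diagonal,
$S_\lambda = (1-\lambda)S + \lambda\,\mathrm{diag}(S)$; when $S$ is not
positive definite the blend escalates automatically through
$\lambda \in \{0.01, 0.1, 0.5, 1\}$. This matters because a group can have as
few as ~11 strides in a class against 54 features. Class imbalance is
retained (priors follow training proportions; no resampling).

Greedy forward selection adds, at each step, the feature minimizing the
stratified k-fold cross-validated misclassification error, stops at the first
step with no strict improvement, and breaks ties by the lowest column index;
with a seeded fold assignment the whole chain is deterministic. Window-length
optimization refits the reduced model on a 100–500 ms grid in 33 ms steps
(13 candidates, 100 … 496 ms), ties to the shortest window. The default
feature-extraction window is 300 ms; where the selection stage's own window
is ambiguous we expose it as a parameter defaulting to the same 300 ms, and
"starting value" means the first sample *of the window*, not of stance.

Note an honest property of the permutation-null check: with 54 features and a
few hundred strides, cross-validated LDA under permuted labels lands slightly
*below* the nominal chance rate (a known small-sample anti-learning effect),
so the null is checked against binomial bounds around chance on a balanced
design rather than against an exact 20 %.

## Sensitivity statistics

The subject-independent sensitivity of DMAMA to a driver (stiffness code, or
incline in degrees) is computed exactly as the mixed-effects description
prescribes operationally: per-subject condition means, then least squares
with a common slope and one intercept per subject; the slope's Wald p-value
(α = 0.05) and the R² on the means are reported. A stride-level
random-intercept variant (`method = "strides"`, via lmerTest) is provided,
but the means-based fit is the default because it is the described
computation; we claim no reproduction of published p-values from either.
Stiffness is coded 0/1/2 so slopes read "per stiffness increment"; N/mm
values are deliberately not used. Stairs never enter incline fits.

How well the pooled trend explains one subject's stride-to-stride data is
measured by a cross-fit $R^2 = 1 - RSS/TSS$, where each stride is first
adjusted for the subject's random effect. The adjustment formula is not
published; we subtract the subject's fitted intercept offset relative to the
grand (mean) intercept, which makes $R^2 = 0$ exactly when the pooled
prediction equals the subject mean and allows negative values when the
pooled trend fits worse than that mean. By least-squares optimality the
cross-fit $R^2$ never exceeds the subject's own-fit $R^2$.

The stiffness × incline interaction is an ordinary multiple regression of
stride-level DMAMA on `[1, k, g, k·g]` over the three incline conditions,
with classical t-based 95 % confidence half-widths. Subject intercept spread
is deliberately left in the residual there (the design is balanced, so slopes
are unbiased and their intervals conservative).

## Numerical choices and degenerate inputs

- Trapezoidal integration on measured timestamps: second-order accurate on
  nonuniform grids without assuming smoothness; window endpoints are
  interpolated. At ~150 Hz sampling of ~0.7 s stances the integration error
  is below 0.05 % (validated against a 10 kHz grid).
- Rotation averaging fixes the angle branch to [0, π); samples within 1e−6 of
  π are rejected rather than sign-flipped, since element-wise vector
  averaging is meaningful only on a consistent branch and mounting
  orientations are never near a half-turn. The final matrix is re-projected
  onto SO(3) (polar projection) to absorb floating-point drift.
- Strides with a force-impulse magnitude below 1 N·s are flagged invalid and
  excluded from statistics rather than raising errors (a zero impulse makes
  the ratio undefined).
- A subject observed at a single driver level contributes only to its
  intercept (with a warning); constant subject data make the cross-fit R²
  undefined (NA, with a warning); rank-deficient interaction designs error,
  naming the collapsed term.
- All randomness flows from a single integer seed; identical configs and
  seeds reproduce byte-identical artifacts, and every output file records the
  seed and a hash of the configuration.

## Problem sizes used in validation

The test suite and the acceptance script validate at: full default sessions
(4 × 3 × ~98 strides ≈ 1176) for the classifier and end-to-end checks;
100 Monte-Carlo replicates for calibration recovery (300 samples, 1°
noise), for stiffness-slope recovery at 3.749 %FL/increment (down-ramp
stratum), and for interaction-model recovery at (3.01, 0.413, −0.145);
100 strides for the fine-grid integration comparison; and a balanced
300-stride single-trial session for the permutation null. Parameter-recovery
replicates draw stride tables directly from the generative linear model
(`simulate_dmama_table()`, which reproduces exactly the targets
`generate_session()` embeds), because the signal chain's fidelity to those
targets is established separately by the noise-free end-to-end test.

## Limitations

The ankle "joint center" of a prosthesis is a chosen physical point, so the
lever arm — and with it DMAMA — carries a possible constant offset relative
to a biological ankle definition; sensitivities (slopes) are unaffected.
Marker-based measurement of the calibration samples, IMU-based mode
labeling, swing-phase dynamics, center-of-pressure reconstruction, and
frontal/transverse moments are out of scope. The classifier is
subject- and stiffness-dependent by design; subject-independent
classification is untested territory here.
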
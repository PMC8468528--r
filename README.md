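# dmama

Gait analysis for semi-active lower-limb prostheses from a single
pylon-embedded six-axis load cell.

Semi-active prosthetic feet (for example a variable-stiffness foot, whose
motor adjusts the free length of its cantilever forefoot spring) can change
one mechanical property once per stride, but need a whole-stance summary of
ankle loading to close the control loop. The **dynamic mean ankle moment arm
(DMAMA)** is that summary: the ratio of the stance-phase sagittal
ankle-moment impulse to the magnitude of the sagittal ground-reaction-force
impulse,

```
DMAMA = J / I = ∫[HS→TO] M_ankle dt  /  ‖ ∫[HS→TO] F_sagittal dt ‖ ,
```

a length — the mean moment arm of the ground reaction impulse anterior to the
ankle — reported here in mm and as a percentage of foot length. Because the
load cell sits in the pylon rather than at the ankle, the ankle (and knee)
moments are obtained by quasi-static moment transport,
`M_joint = (r × F_sagittal)_z + M_sagittal`, with `r` the joint-to-sensor
lever arm, after rotating the raw stream into the shank frame with a
calibration rotation estimated by rotation-vector averaging of repeated
orientation samples.

The package implements the full chain, for researchers in prosthetics and
wearable-sensor biomechanics:

- **Synthetic gait sessions** (`session_config()`, `generate_session()`):
  load-cell-frame wrench streams over five locomotion modes (level, ±5° ramps,
  stairs up/down) and three stiffness settings, with jittery sampling
  (149.9 ± 38.5 Hz), sensor noise, flagged transition strides, and per-stride
  ground-truth DMAMA following a linear stiffness × incline model with
  subject-specific intercepts.
- **Frame calibration** (`average_rotation()`, `average_offset()`,
  `to_shank_frame()`).
- **Stride pipeline** (`detect_events()` — 8 % body-weight threshold on the
  sagittal force, `segment_strides()` with transition exclusion,
  `resample_uniform()` for the classifier path).
- **DMAMA metric** (`joint_moments()`, `compute_dmama()`,
  `moving_average_dmama()`), trapezoidal integration on the measured
  (nonuniform) timestamps.
- **Locomotion-mode classifier** (`build_feature_table()`,
  `forward_select()`, `optimize_window()`, `train_eval_lda()`): 9 load-cell
  channels × 6 statistics = 54 features from a pre-toe-off window,
  subject- and stiffness-dependent LDA with stratified 10-fold
  cross-validation.
- **Sensitivity analysis** (`fit_subject_independent()`,
  `fit_subject_dependent()`, `crossfit_r2()`, `fit_interaction()`):
  DMAMA sensitivity to stiffness and incline with subject intercepts, and the
  stiffness × incline interaction regression.
- **Orchestration** (`run_pipeline()`, plus a thin command-line wrapper in
  `inst/cli/dmama_tools.R`).

## Worked example

```r
library(dmama)
cfg <- session_config(seed = 1)   # 4 subjects x 3 stiffnesses x 5 modes
report <- run_pipeline(cfg)       # simulate -> calibrate -> segment -> DMAMA
                                  #   -> classify -> sensitivity
report
#> <pipeline_report> seed 1, 1176 strides (1176 valid, 48 excluded)
#>   classifier accuracy: 100.00%
#>   stiffness sensitivity by mode: down_ramp=4.00, level=2.83, up_ramp=2.60,
#>     down_stairs=2.68, up_stairs=3.35

fit_subject_independent(report$dmama, "stiffness", stratum = "down_ramp")
#> <sensitivity_fit> subject_independent, driver stiffness, stratum down_ramp:
#>   slope 4.001 %FL/unit, p = 9.96e-08, R^2 = 0.990 (n = 12)

fit_interaction(report$dmama)
#> <interaction_fit> n = 864 strides
#>   intercept    10.929 +/- 0.400
#>   stiffness     2.975 +/- 0.310
#>   incline       0.408 +/- 0.145
#>   interaction  -0.140 +/- 0.112
```

The 1176 strides are every detected stance; the 48 excluded ones span a
locomotion-mode boundary (transition steps). The down-ramp fit says DMAMA
moves 4.0 % of foot length anteriorly per stiffness increment in this
session (the generator drew per-stride noise around its 3.01 %FL/increment
model with a −0.145 interaction, so the within-mode slope at −5° incline is
3.01 − 5·(−0.145) ≈ 3.7). The interaction regression recovers the generating
coefficients within their 95 % confidence half-widths. A controller would
act on `moving_average_dmama()` rather than single strides.

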
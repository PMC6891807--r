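---
title: "Methods: two-sensor gait kinematics and phase-difference analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sensor gait kinematics and phase-difference analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

# The measurement model

Two inertial sensors are strapped to one leg: sensor A on the thigh,
sensor B on the shin, both mounted facing the same way. Each sensor's
onboard fusion emits its orientation as a scalar-first unit quaternion at
a fixed rate. `gaitphase` treats the leg as a serial kinematic chain in
which the hip and knee are each three coincident revolute joints. The six
Denavit–Hartenberg links are fixed:

| link | θ (variable) | d  | a | α     |
|------|--------------|----|---|-------|
| 1    | θ1           | 0  | 0 | −90°  |
| 2    | θ2           | 0  | 0 | +90°  |
| 3    | θ3           | dA | 0 | 0°    |
| 4    | θ4           | 0  | 0 | −90°  |
| 5    | θ5           | 0  | 0 | +90°  |
| 6    | θ6           | dB | 0 | 0°    |

Each link contributes `Rotz(θ)·Transz(d)·Transx(a)·Rotx(α)`
(`dh_transform()`); the triad products `T_A0 = A10·A21·A32` and
`T_BA = A43·A54·A65` are implemented from their closed forms
(`compose_hip_transform()`, `compose_knee_transform()`) and tested
entrywise against the explicit per-link products. The link offsets `dA`,
`dB` (thigh and shin lengths) only translate; no joint angle depends on
them, so both default to 1 and the method is orientation-only.

The global frame is taken as identity, so the thigh sensor's calibrated
orientation *is* `T_A0`, and the knee transform is recovered as
`T_BA = T_A0⁻¹ · T_B0` (`relative_transform()`).

## Calibration

At the start of a recording the subject holds the leg in an aligned pose.
For each sensor the reference orientation is the sign-aligned, normalized
component mean of the first `n_init` quaternions, and every sample is
right-multiplied by the inverse of that reference
(`calibrate_stream()`), which forces the calibrated transform at the
reference pose to identity. Right-multiplication removes a sensor-frame
(mounting-side) offset: if the raw series is `S(t)·M` with a fixed mount
`M` and `S(0) = I`, calibration returns exactly `S(t)`. A world-frame
(left) offset is *not* removed — it is conjugated into the series — and
the test suite pins down both behaviours. A `side = "left"` option
applies the alternative convention for users whose rig is described that
way, without any claim that one convention is universally correct.

`n_init` defaults to 1 (the aligned pose is a single posture in
principle), but with real, noisy sensors a single-sample reference
freezes that sample's orientation noise into a constant misalignment of
the whole series. The misalignment couples into the small-amplitude
frontal/transverse knee channels with gain `1/sin θ5`, *coherently at the
gait frequency*, which no downstream filtering can undo. Averaging a
short hold is the remedy: the simulator therefore emits a 0.5 s
aligned-pose hold (`n_calib = 50` samples at 100 Hz) and recovery
analyses calibrate with `n_init = n_calib`. This reduced worst-case
phase-recovery errors from ~8° to ~3° at the default noise level.

## Inverse kinematics and the singular pose

The default `atan2` mode recovers signed angles:
`θ2 = atan2(√(r31²+r32²), r33)`, `θ3 = atan2(r32, −r31)`,
`θ1 = atan2(r23, r13)` (identically for θ5, θ6, θ4 on `T_BA`). The
`acos` mode implements the principal-range closed forms
(`θ2 = acos r33`, `θ3 = acos(−r31/sin θ2)`, `θ1 = acos(r13/sin θ2)`);
both agree wherever the `acos` form is defined, which the suite checks to
1e-9°.

At `sin θ2 = 0` the triad decomposition is degenerate, and the
calibration *guarantees* this pose occurs (the calibrated initial sample
is identity). The policy (`singular_policy`): report θ2 as 0° or 180°
from the sign of `r33`, set θ3 to 0°, and let θ1 absorb the combined z
rotation `atan2(r21, r11)`. A `"hold"` variant carries the last resolved
θ1/θ3 forward through a singular gap. Singular samples are counted in a
message and flagged in the result, never an error. The threshold is
`|sin θ2| < 1e-6` — tight on purpose: it identifies exact degeneracy, not
noisy near-degeneracy, and the phase module handles the latter by
excluding the calibration hold (below).

# Phase analysis

Each joint-angle channel is reduced to its normalized instantaneous
signal (`normalize_signal()`): central-difference temporal derivative,
mean removed, scaled to unit peak. Differentiation annihilates constant
offsets exactly; a linear drift differentiates to a constant that the
mean removal strips. This is what makes the phase estimates insensitive
to the two dominant IMU error modes (offset and slow drift), and the
invariance is tested at the rated 5°/h drift.

The gait cycle frequency is estimated from the hip sagittal channel (the
strongest oscillation): coarse periodogram peak inside a 0.3–3 Hz band,
then continuous refinement of the DFT magnitude of the analytic signal
around that bin (the analytic signal carries no negative-frequency image,
whose leakage would bias the peak of a plain real-signal DFT). The
estimate is kept unrounded internally; displayed values are rounded to
two decimals. An estimation error is raised when no in-band peak clears
20× the median in-band power (no gait rhythm), or when the series covers
fewer than 3 cycles.

The hip–knee time lag Δt is estimated per plane pair, by default as the
circular mean of the instantaneous phase difference of the two analytic
(discrete Hilbert) signals divided by 2πf, with 10% of samples trimmed at
each edge against Hilbert edge effects; this resolves lags in
(−1/(2f), 1/(2f)]. The alternative `xcorr` estimator takes the
cross-correlation peak (parabolic sub-sample refinement) over the same
window, widened to a full cycle with `extend = TRUE`. Positive Δt means
the knee waveform trails the hip. The phase-difference angle is the
literal product `φ = 360·f·Δt`, never reduced modulo 360, so the stored
rows satisfy the identity exactly.

Before any of this, `phase_profile()` drops the calibration window (the
series' `n_init` leading samples, plus any further leading
singular-flagged run). The hold is not gait, and under measurement noise
its samples sit *near* (not at) the singularity, where θ4/θ6 decompose to
ill-determined values whose derivative spikes would leak through the
Hilbert transform far into the series — in testing this was the single
largest error source, worth up to 12° of φ. Externally supplied angle
CSVs carry no such metadata, so the CLI `phase` command exposes
`--skip N`.

Trial summaries use plain linear mean and sample SD per plane pair
(matching how repeated-trial tables are conventionally reported), with a
circular-statistics alternative behind a flag.

## Classification

The classifier is a deliberately simple threshold rule on the sagittal
φ: at or above 45° → normal; at or below 0° → hemiplegic; between →
indeterminate, with the distance to the nearest boundary as a score. The
thresholds sit between the prototype means of the two patterns (~+100°
normal, ~−60° hemiplegic) with a wide indeterminate buffer. It is a
heuristic calibrated to those prototypes — not a validated clinical
classifier — and every report it writes carries that disclaimer verbatim.

# The simulator

`gait_model_params()` defines the synthetic study conditions: each joint
angle is a single cosine `mean_j + amp_j·cos(2πf·t − ψ_j)` (an optional
`harmonics` hook adds higher terms, since real joint trajectories are not
monochromatic), preceded by the aligned-pose hold. Defaults: 30 s at
100 Hz; hip flexion 30°±20°, knee flexion 35°±25°, ±5–8° in the other
planes — plausible adult walking ranges; the validated invariants keep
θ2/θ5 at least 5° away from the IK singularity and require ≥10 samples
per cycle and ≥3 cycles. The `normal` preset walks at a 1.3 s cycle with
knee-vs-hip phase offsets (101.41°, 91.70°, −155.63°) for the
sagittal/frontal/transverse pairs; the `hemiplegic` preset at 1.8 s with
reduced knee amplitudes (stiff knee) and offsets (−62.61°, −27.22°,
−10.26°). These offsets are prototypes of the two coordination patterns,
not a biomechanical model of circumduction, and the amplitudes are not
claimed to be clinically representative. The transverse normal prototype
is stored as its wrapped equivalent (−155.63° rather than +204.37°):
phase is defined modulo one cycle, the default estimator resolves lags
within (−180°, 180°], and recovery tests compare circularly; the
extended-window `xcorr` estimator can report the unwrapped value.

`forward_compose()` runs the chain forward (hip triad → thigh quaternion;
hip·knee → shin quaternion) and applies mounting rotations on a
configurable side — `"right"` (sensor-frame, removed by calibration) by
default; the `"left"` case is kept because the tests use it to document
what calibration does *not* remove. `add_imu_noise()` right-multiplies
each sensor independently with: white Gaussian angle noise about random
axes (default 0.2° per sample); a random-walk drift whose step size is
calibrated so the expected accumulated drift magnitude over the stream
equals the rated degrees-per-hour (default 5°/h, checked by Monte Carlo
against the chi-distribution expectation); and an optional constant
offset rotation per sensor. Everything is deterministic under a fixed
seed.

What the simulator does *not* emulate: gait-cycle-to-cycle variability,
event asymmetries (heel strike/toe off), soft-tissue artefact,
magnetometer disturbance, or sensor dropout. Passing the recovery suite
therefore shows the pipeline is correct and robust to the modelled error
modes — not that the classifier is clinically valid on real recordings.

# Numerical choices and problem sizes

- Degrees at every interface, radians internally; quaternions
  scalar-first, normalized on read, rejected beyond a 1e-3 norm deviation.
- Rotation→quaternion conversion uses the four-branch (largest
  pivot) method; quaternion means are sign-aligned before averaging to
  respect the double cover.
- Recovery and invariance tests run at 30 s × 100 Hz (≈3000 samples per
  trial), 1000-draw FK→IK sweeps, and 50–100 seeded repetitions for the
  stochastic checks — sizes at which every suite completes in seconds
  while leaving Monte-Carlo error well below the tested tolerances.
- Known limitations: the analytic lag estimator cannot distinguish φ
  from φ±360° (inherent to phase); near-singular *noisy* poses inside a
  gait trajectory (knee flexion under ~10° with coarse sensors) inflate
  frontal/transverse noise by 1/sin θ5, which is physics, not an
  implementation artefact; and the `acos` IK mode loses angle signs by
  construction and is retained only for fidelity to the principal-range
  closed forms.
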
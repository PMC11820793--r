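---
title: "Estimating the whole-body COM in single-leg standing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the whole-body COM in single-leg standing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slscom)
```

# The estimation problem

During single-leg standing the clinically interesting balance variable is
the horizontal displacement of the whole-body center of mass (COM), in the
anteroposterior (AP, X) and mediolateral (ML, Y) directions. `slscom`
estimates it from a force platform under the stance foot and three IMUs:
occiput, non-stance thigh, non-stance lower leg. The body is decomposed
into a *main system* (stance leg + upper body, a linearized double
inverted pendulum pivoting at the ankle and the stance hip) and a
*subsystem* (the non-stance leg, a two-link chain hanging from the swing
hip Q, treated with exact nonlinear inverse dynamics). The two COMs are
fused by their segment masses.

All segment masses, lengths, COM heights and moments of inertia are
standard anthropometric linear functions of subject height H and mass M
(`compute_body_params()`); the five mass fractions sum to one, so total
mass is conserved exactly. This scaling is also the main systematic error
source on real subjects whose build deviates from the scaling tables.

# Sensor processing

## Attitude estimation

Each IMU's roll and pitch are estimated by a two-state extended Kalman
filter: the state (roll, pitch) is propagated with the measured body
rates through the 3-2-1 Euler-angle kinematics, and corrected with the
accelerometer's gravity direction. Tunables (all exposed in
`ekf_config()`):

* `gyro_noise` (0.005 rad/s/√Hz) — process noise of the rate integration.
* `accel_noise` (0.05 m/s²) — accelerometer sensor noise.
* `accel_dynamic_sd` (3 m/s²) — the dominant term of the measurement
  noise. An accelerometer on a moving limb measures gravity *plus* the
  limb's kinematic acceleration; at the swing frequencies of interest
  (≈ 0.75 Hz) those accelerations reach a few m/s², so the accelerometer's
  usefulness as a tilt reference is limited by motion, not by sensor
  noise. The resulting small Kalman gain makes the filter behave like
  gyro integration with a slow gravitational anchor (time constant of a
  few seconds), which is the appropriate regime for these motions.
* `init_cov` (0.1 rad²) and the gate `obs_gate` (0.5): samples whose
  specific-force norm deviates from g by more than half of g (free-fall
  like) are flagged low-observability and bridged by gyro prediction.

The pipeline additionally runs the two swing-leg filters twice
(`predict_sensor_accel()`): the sensors sit at known offsets on a
pendulum anchored at the hip, so the lever-arm acceleration
`ω̇×s + ω×(ω×s)` at each sensor is predictable from the gyros and the
link geometry. Pass one estimates attitudes; pass two subtracts the
predicted kinematic acceleration from the gravity measurement. This
removes the systematic tilt bias that sustained rotation would otherwise
induce — most visibly the DC centripetal acceleration during the yaw
condition, which a purely gravity-referenced filter cannot distinguish
from tilt.

Yaw is unobservable from gravity and the magnetometer is deliberately
not used; instead the thigh and lower-leg yaw rates about the vertical
are assumed equal (the knee does not twist appreciably), their
stationary-frame vertical rates are averaged, and the shared rate is
integrated by the forward Euler method from zero initial yaw
(`integrate_yaw()`). Averaging two sensors halves the rate-noise
variance; the zero-mean-noise drift grows only as σ√n/fₛ. The head
sensor's yaw is fixed at zero (the subject faces forward; head yaw does
not enter the estimator's equations at first order).

Accelerations are rotated to the stationary frame and gravity is
removed, `a = T f − (0,0,g)`; because the sensors are mounted at segment
COM height these are taken as segment-COM accelerations. The generator
can also emit gravity-free readings (`accel_kind = "kinematic"`), which
pins the gravity-handling convention down in tests.

## Filtering

The horizontal plate forces are small and drift-prone, so they pass a
zero-phase high-pass at 0.1 Hz before entering the solver; estimated COM
and COP pass a zero-phase low-pass at 3 Hz. The filter family and order
are not dictated by the measurement model; a 4th-order Butterworth run
forward and backward is the standard biomechanics choice and is what
`filter_spec()` defaults to. The implementation pads with odd
(point-symmetric) reflection — up to two periods of the cutoff
frequency — and starts each pass from a DC-consistent internal state, so
constants are rejected (high-pass) or passed (low-pass) without step
transients. Gyro numerical differentiation (needed for the rigid-body
moment terms) uses central differences at interior samples and one-sided
differences at the edges; optional gyro pre-smoothing is available but
off by default, since the 3 Hz output filter already bounds the noise
this injects.

# The estimator

## Swing-leg inverse dynamics

Segment COMs follow from the attitudes and the rigid-link geometry: the
COM height `l` is measured from the distal (bottom) end of each segment,
so the thigh COM sits `L_s1 − l_s1` below the hip along the thigh axis.
Per segment, `R_si = −m_si a_si + m_si g_vec` is the force the segment
exerts on its surroundings, and
`N_si = T_si (J_si ω̇̃ + ω̃ × J_si ω̃)` its rotational term. The moment
balance of the chain about the instantaneous hip joint gives the wrench
transmitted to the main system:

`R_s = R_s1 + R_s2`,  `N_s = −N_s1 − N_s2 + r_s1×R_s1 + r_s2×R_s2`.

The sign of the transport (cross-product) terms follows from the moment
theorem about Q and is confirmed by the static oracle in the test suite:
a hanging tilted leg must load the hip with a moment equal to its weight
times its horizontal COM offset, and the static fused COM must land on
the COP. The hip joint is treated as a fixed point of the hip-anchored
frame; its own acceleration (a few mm at sway frequencies) is a
second-order effect here because the force balance uses measured — hence
complete — segment accelerations.

## Main-system solves and sign conventions

`force_plate_series` stores the *ground-reaction* wrench (vertical force
positive upward, moments of the reaction about the plate origin; axes X
forward, Y left, Z up). The balance equations are conventionally posed in
terms of the subject-on-plate (action) force and moment, so the solver
negates the horizontal force and moment channels when assembling
right-hand sides. The COP follows the reaction convention:
`COP_X = (−N_y − R_x h)/R_z`.

Each plane solves a per-sample 3×3 system (force balance; moment balance
about the plate origin; head-acceleration constraint). The moment-row
coefficients were re-derived from the momentum balance of the main
system about the plate origin; the coefficient structure
(`A21, A22, A23` sagittal, `B21, B22, B23` frontal, recorded on the
solution object and echoed in the run log) contains one deliberate
approximation: the hip's horizontal position is expressed through the
main-system COM as `(L_m1/l_m)·X_m`, which is exact when both segments
tilt as one. The matrix is re-assembled each sample because the third
coefficient depends on the instantaneous vertical hip load; samples
whose condition number exceeds `1e10` are flagged and held at the
previous valid solution (an all-singular series is an error), and the
relative back-substitution residual is recorded per sample.

One property of this formulation deserves emphasis. In the solver's
coefficient `A23 = [(m_m1+m_m2)g − R_sz]·L_m1/l_m` the factor `L_m1/l_m`
multiplies the *gravity* term as well, although the strict moment
balance attaches it only to the hip-load term. The estimator keeps this
form deliberately: the resulting mild overestimate
of the main-system displacement compensates, almost exactly at this
model's mass distribution, for the hip horizontal displacement that the
COM fusion step ignores (see below). Correcting either one alone makes
the closed-loop estimate *worse*; the pair behaves as a consistent,
self-compensating approximation, and the closed-loop tests lock this
behaviour in.

## Fusion and metrics

The whole-body COM is the mass-weighted combination of main-system and
subsystem COMs, with the inter-hip distance `w` offsetting the swing-leg
chain towards the swing side (`+` for a right stance leg); the stance
foot (1.1 % of body mass) is static and not part of the moving body. The
hip's horizontal displacement is ignored during fusion — the
approximation discussed above.

`com_metrics()` reports Pearson's r and the RMSE over an evaluation
window, by default samples 1001–4000 (10–40 s at 100 Hz): the first ten
seconds keep filter and estimator transients out of the score, the last
five keep filter edges out. The RMS of the reference is computed about
its mean (the sway-amplitude convention used for normalized accuracy,
RMSE/RMS); a constant reference yields `r = NA` with a warning. For COP
comparison plots the file pipeline also writes mean-removed series,
since sway traces are conventionally plotted about zero.

# The synthetic generator

`generate_trial()` prescribes each segment's 3-2-1 Euler angles as sums
of sinusoids (optionally ramped in over 3 s by a smooth half-cosine
envelope — metronome-paced movements start from rest), so every
kinematic quantity has a closed form. The ground-reaction wrench is the
exact nonlinear Newton–Euler balance of all five segments, including the
rotational terms; the IMU streams are synthesized at the sensor poses
(segment COM height; head sensor at the top of the upper-body segment,
whose acceleration is exactly what the head-constraint row of the solver
consumes). The prescribed-trajectory design is intentional: ground truth
must be exact and cheap, and a feedback-stabilized human simulator is a
non-goal.

Study conditions (defaults chosen once as realistic for this task):

* **A_quiet** — postural sway with COM amplitude components of 6 mm at
  0.3 Hz plus 2 mm at 0.7 Hz (AP) and 4 + 1.5 mm (ML), chosen so the
  resulting sway RMS is of the order reported for young adults in this
  task; the upper body tilts 15 % more than the leg (`upper_gain`) so
  the two segments are not artificially rigid. The swing thigh is raised
  30° with a small incidental wobble (0.5°).
* **B_updown** — thigh and shank pitch oscillate by 10°/15° at 0.75 Hz.
* **C_yaw** — both swing segments share a ±15° yaw oscillation at
  0.75 Hz (the shared-rate assumption of the estimator is exact in the
  generator; what the closed loop tests is the Euler integration and the
  estimator chain, not that assumption).

Two generator choices matter for interpretation:

* **Balanced foot placement.** The stance-foot COM defaults to the
  ground projection of the baseline-pose moving-body COM, emulating a
  subject who aligns their support under their COM. The foot's weight
  moment about the plate origin is not part of the estimator's model, so
  a foot COM far from the body's mean COM projection introduces a
  constant offset of order `(m_f/M)·(COM offset)` — about 1 % of the
  lateral COM excursion — into the COM-vs-COP comparison. The static
  equilibrium fixture additionally adducts the raised swing leg by
  28.5° so its COM hangs near the body midline: with near-zero static
  COM offsets the equilibrium property (fused COM = COP) can be tested
  at the 0.1 mm level without being dominated by that constant
  foot-mass term.
* **Main-segment vertical inertia.** The anthropometric table provides
  no yaw-axis inertia for the stance leg and upper body (they do not yaw
  in this model); the generator uses the mean of the two transverse
  values for the exact rotational terms. This affects nothing the
  estimator consumes.

Noise (`noise_spec()`) adds white Gaussian noise per channel
(accelerometer 0.02 m/s², gyro 0.2°/s, plate force 0.5 N, plate moment
0.1 N·m by default) and an optional fixed gyro bias drawn from the trial
seed; the seed fully determines the trial, and generation is
bit-reproducible. The gyro-bias default is zero: bias mainly drives yaw
drift, which is a separately explorable effect rather than part of the
baseline noise scenario.

What the generator does **not** emulate: feedback balance control and
its characteristic sway spectra, soft-tissue artefacts, sensor mounting
misalignment (a config hook exists but defaults to identity), foot
compliance and COP travel under a deforming foot, plate drift (the
high-pass is exercised spectrally, not against a drift model), and
magnetometer disturbances (no magnetometer is modelled at all). Passing
closed-loop tests therefore demonstrates the estimator chain's internal
consistency and noise behaviour, not its robustness to those real-data
effects.

# Diagnostics and numerical choices

`linearization_residual()` evaluates, on ground truth, the main-system
moment balance with gravity and the hip-wrench transport kept exact and
only the pendulum inertia linearized. Two facts guide its use. First,
for sway symmetric about the vertical the leading linearization error is
*cubic* (the sine expansion is odd), and this model's near-isotropic
segment inertias suppress the usual gyroscopic quadratic terms; a
quadratic regime only appears for sway about a small constant lean,
where the `m·x̄·z̈` transport term (∝ lean × amplitude²) dominates. The
scaling fixture therefore sways about a 0.4° lean, where the residual's
amplitude-doubling ratio sits at the quadratic value of 4. Second, the
solver's coefficient `A23` differs from this strict balance by
the first-order compensation term discussed above; the diagnostic is
about the physics of linearization, not a re-statement of the solver.

Problem sizes used by the test suite are the package's own choices:
full-length trials (45 s at 100 Hz, scored over 10–40 s) for the
closed-loop and noise checks, 8–20 s trials for module-level properties.
The whole suite, including all closed-loop runs, completes in well under
a minute.

# Known limitations

* Linearized main system: leans or sway beyond a few degrees violate
  the small-angle regime, and the generator refuses presets whose main
  tilt reaches 5°.
* The subject-specific accuracy of the anthropometric scaling is not
  addressed (no per-segment calibration in this version).
* Head motion independent of the trunk violates the head-constraint row.
* The absolute COM position carries small constant offsets (foot-mass
  moment, inter-hip geometry); displacement-style analyses (mean-removed
  traces, correlation, RMSE of displacement) are the intended use.
* Yaw of the swing leg rests on rate integration from zero; long trials
  with biased gyros will drift, which is why the deliberate yaw
  condition exists as a stress test.
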
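---
title: "Estimating lower-limb gait kinematics from a seven-IMU array: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb gait kinematics from a seven-IMU array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

imugait estimates 3D lower-limb kinematics — hip, knee and ankle joint
angles, per-stride ranges of motion (ROM), stride length (SL) and step width
(SW) — from a seven-sensor array of body-worn inertial measurement units
(IMUs): one per foot, shank, thigh, and one on the pelvis. This vignette is
the package's own account of the underlying models, the tunable parameters,
the synthetic test bed, and the numerical and design choices a user or
reviewer should know about.

## The estimation problem

Each IMU delivers specific force $a$ (m/s$^2$) and angular rate $\omega$
(rad/s) in its own sense frame at a fixed rate (128 Hz by default).
Integrating these signals directly — *strapdown integration* — propagates
each sensor's position $p$, velocity $v$ and orientation quaternion $q$, but
sensor noise makes the integrated pose drift without bound. The package
corrects that drift with an **error-state Kalman filter (ErKF)** over all
seven IMUs jointly.

### State and error state

The nominal state per IMU is $(p, v, q)$ with $q$ a Hamiltonian unit
quaternion rotating sensor-frame vectors into the world frame (world: $z$
up, gravity $g = (0,0,-9.81)$ m/s$^2$). The filter tracks the small
*error state* $(\delta p, \delta v, \delta\theta)$ per IMU — 9 states per
sensor, 63 for the full array — whose mean is identically zero between
updates; only its covariance $P$ is propagated. The attitude error is a
3-vector applied **right-multiplicatively**, $q \leftarrow q \otimes
\exp(\delta\theta)$; every measurement Jacobian in the package is derived
under this convention and verified against central finite differences of
the corresponding nonlinear map (tolerance $10^{-5}$, part of the test
suite).

### Prediction

Strapdown integration per IMU and time step $\Delta t$:

$$p \leftarrow p + v\,\Delta t + \tfrac12 (R a + g)\Delta t^2,\qquad
  v \leftarrow v + (R a + g)\Delta t,\qquad
  q \leftarrow q \otimes \exp(\omega \Delta t),$$

with $R$ the rotation matrix of $q$. The covariance propagates as
$P \leftarrow F_x P F_x^T + Q$ where $F_x$ is block-diagonal over IMUs and
$Q$ carries $\sigma_a^2 \Delta t^2$ and $\sigma_\omega^2 \Delta t^2$ on the
velocity and attitude blocks (zero on position). One deliberate refinement:
the position–attitude block of $F_x$ keeps its exact value
$-\tfrac12 R [a]_\times \Delta t^2$ rather than the customary zero
truncation, so the analytic Jacobian matches finite differences of the
implemented map to first order; at 128 Hz the truncation error would be
$\sim 10^{-4}$, fifteen times the verification tolerance.

### The four measurement corrections

All corrections are *pseudo-measurements* of quantities whose true value is
known, applied in one batch per time step (a single stacked $H$, $z$, $C$;
gain solved through a Cholesky factorisation with $10^{-12}$ jitter
escalation, never an explicit inverse):

1. **Zero-velocity update (ZUPT)** — at one detected *footfall* instant per
   stance, the foot IMU's velocity is observed to be zero
   ($\sigma_{ZV} = 0.01$ m/s). This is the primary position-drift
   corrector.
2. **Gravitational tilt** — a still IMU's accelerometer direction observes
   gravity: $h(x) = R^T \hat z$, $z = a/\lVert a\rVert$
   ($\sigma_{tilt} = 5.73^\circ$). Events are suppressed when
   $\lVert a \rVert \notin [0.8, 1.2]\,g$, rejecting dynamic contamination.
3. **Joint center** — at every time step and all six joints, the
   world-resolved joint center computed from the two adjacent IMUs must
   coincide: $h(x) = (p_1 + R_1 r_1) - (p_2 + R_2 r_2)$, $z = 0$
   ($\sigma_{JC} = 0.01$ m). This couples the seven single-IMU filters into
   one multi-body estimator.
4. **Joint axis ("soft hinge")** — at every time step, the
   flexion/extension axes of the two segments adjacent to each knee and hip
   are observed to align in the world frame:
   $h(x) = R_1 e_1 - R_2 e_2$, $z = 0$. The knee is nearly a hinge during
   gait, so its noise is tight ($\sigma_{JA,knee} = 1.15^\circ$); the hip
   rotates freely in three degrees of freedom, so its correction is fifty
   times softer ($\sigma_{JA,hip} = 57.3^\circ$) — it only nudges the hip
   towards anatomically plausible configurations, counteracting the slow
   internal/external-rotation drift that joint-center corrections alone
   leave unobservable. No axis correction is applied at the ankle.

After each update the error mean is injected into the nominal state
(quaternions through the exponential map with its analytic zero-angle
limit) and reset to zero; the covariance update
$P \leftarrow G (I - K H) P G^T$ includes the reset Jacobian $G$, which is
identity except for $I - [\tfrac12\hat{\delta\theta}]_\times$ on the
attitude blocks (computed from the just-estimated error). Steps with no
events pass the prediction through unchanged, so disabling all four
corrections reproduces raw strapdown integration bit-for-bit — that
equivalence is a test.

### Default noise values

`noise_config()` defaults: $\sigma_a = 0.013$ m/s$^2$,
$\sigma_\omega = 2.83$ deg/s, $\sigma_{ZV} = 0.01$ m/s,
$\sigma_{tilt} = 5.73$ deg, $\sigma_{JC} = 0.01$ m,
$\sigma_{JA,knee} = 1.15$ deg, $\sigma_{JA,hip} = 57.3$ deg — IMU-grade
sensing at 128 Hz. Degree-valued arguments are converted once at
configuration; all internal math is SI radians. The initial covariance
(never a published quantity; a package choice) defaults to
$\sigma_{p0} = 0.01$ m, $\sigma_{v0} = 0.01$ m/s, $\sigma_{\theta 0} =
1^\circ$ per IMU, configurable through `initial_covariance()`.

## Event detection

`detect_still()` flags a sample still when (a) the raw gyroscope magnitude
is below 60 deg/s and (b) the rolling standard deviation of the
accelerometer magnitude over 0.15 s is below 0.08 m/s$^2$; maximal runs of
at least 0.05 s become still intervals. Condition (b) deserves a note: a
gyro-only criterion also fires on segments that rotate slowly while
*accelerating* (the thigh and shank during stance, the pelvis more or less
continuously), and the resulting tilt corrections observe the direction of
gravity-plus-dynamic-acceleration rather than gravity. On noise-free
synthetic data this injected joint-angle errors two orders of magnitude
above the otherwise machine-precision regime. A genuinely still sensor
reads a locally constant $\lVert a \rVert = g$; requiring accelerometer
stationarity is the standard compound still-detector design in foot-mounted
inertial navigation and is what "momentarily still" is taken to mean here.
Both conditions use only signal norms, so detection is invariant to any
fixed rotation of the sensor frame (a property test).

`detect_footfalls()` selects exactly one instant per qualifying still
interval (at least 0.1 s long) of a foot IMU: the sample minimising
$\lVert\omega\rVert + \lambda\,\bigl|\lVert a\rVert - g\bigr|$ with
$\lambda = 1$ s, ties broken to the earliest index. One footfall per stance
feeds one ZUPT; all still samples of any IMU feed tilt events.

## From IMU poses to gait metrics

**Segment orientations.** The calibration supplies, per segment, the
anatomical-to-sensor rotation $R_{AS}$ (composable from cluster factors via
`compose_ras()`, $R_{AS} = R_{CS} R_{AC}$); the world-from-anatomical
rotation is $R_{WA} = R_{WS} R_{AS}$. `fit_rotation_by_angular_velocity()`
recovers a fixed sensor-to-reference rotation as the orthogonal Procrustes
minimiser of the angular-velocity residual (SVD with determinant
constrained to $+1$) — the standard way to obtain $R_{CS}$ by comparing raw
gyro data against a tracked marker cluster's angular velocity.

**Joint angles.** For each joint the relative rotation
$R_{rel} = R_{WA,prox}^T R_{WA,dist}$ is decomposed in the body-fixed
**Z-X-Y** joint-coordinate sequence: flexion/extension about the proximal
medial-lateral ($z$) axis, internal/external rotation about the distal
longitudinal ($y$) axis, abduction/adduction about the floating $x$ axis.
Anatomical frames are $x$ anterior, $y$ superior, $z$ to the subject's
right. The sequence and the floating-axis treatment are this package's
reading of the joint-coordinate-system convention for the lower limb; the
decomposition is isolated in one function (`joint_angles()`, inverse
`joint_angle_matrix()`) so an alternative convention is a one-line change.
Left-side AbAd and IE are sign-mirrored so positive means
adduction/internal rotation on both sides — a documented convention, since
per-side sign semantics differ across laboratories. For the ankle the same
triple reads dorsi/plantarflexion, inversion/eversion, int/ext rotation;
the ankle is decomposed with the same three-angle machinery even though
skeletal models often constrain it to two degrees of freedom. Near gimbal
lock ($|\cos(\text{AbAd})| < 10^{-6}$, anatomically unreachable) the
decomposition returns `NaN` with a warning.

**Filtering.** Angle series are smoothed with a zero-lag 4th-order
Butterworth low-pass at 6 Hz, applied forward-backward. The design cutoff
is pre-warped by $(\sqrt 2 - 1)^{-1/8}$ ($\approx 1.117$) so the *two-pass*
$-3$ dB point sits at the nominal cutoff; series are reflection-padded
before filtering, and `NA` gaps split the series into segments, with
segments shorter than 0.2 s skipped (they cannot warm the filter up).

**Stride metrics.** The heel path is $p(t) + R(t)\,r_{heel}$ from the foot
IMU pose and the calibrated heel offset. Stride length is the horizontal
(world $xy$) heel displacement between consecutive same-foot footfalls;
step width is the perpendicular distance from the opposite foot's heel at
the intermediate footfall to the *supporting line* of the stride vector
(line, not segment — the collinear lateral-walking case then gives exactly
zero). The first stride and last two strides of a treadmill trial are
transition strides and are dropped. ROM is the within-stride max minus min
per angle; a stride with any missing sample is invalid, and a trial summary
is suppressed for an angle when more than 30% of its strides are invalid.
ROM is invariant to constant offsets in an angle series — the property that
makes ROM comparable across methods even when the underlying waveforms
carry systematic offsets.

## The synthetic gait test bed

No public dataset accompanies the package, so `simulate_gait()` is
first-class, tested code that generates the study conditions: six treadmill
gaits (`forward_slow/normal/fast`, `backward`, `lateral_left/right`) with
per-gait belt speeds (0.47/0.86/1.32, 0.43, 0.39/0.38 m/s) and stride
lengths (0.84/1.09/1.40, 0.62, 0.48/0.46 m) typical of self-selected
treadmill walking; the stride period is their ratio. Forward/backward gaits
use a 0.12/0.15 m step width; lateral gaits place both feet essentially on
one line (0.01 m), which is why their mean step width is near zero.
Trials default to 60 s at 128 Hz.

### Construction: exactness where it matters

The simulator is built so that three properties hold *exactly*, making it
a strict oracle for the filter rather than an approximate one:

1. **Discrete strapdown consistency.** Positions and velocities satisfy
   $p_{k+1} = p_k + \tfrac{\Delta t}{2}(v_k + v_{k+1})$ at every sample.
   `synthesize_imu()` then inverts the process model exactly —
   $a_k = R_k^T((v_{k+1}-v_k)/\Delta t - g)$ and $\omega_k = \tfrac{2}{\Delta t}\log(q_k^* \otimes q_{k+1})$
   — so noise-free synthesised data integrates back to truth at machine
   precision (the packaged tests assert $<10^{-6}$ m over 10 s; observed
   $\sim 10^{-12}$ m). Sampling an analytic trajectory naively would leave
   $O(\Delta t^2) \approx 10^{-4}$ m of quadrature error instead.
2. **Exact foot dwells.** Each foot's ankle trajectory is a root signal
   with analytic velocity that is *identically zero* inside every stance
   dwell window (35% of the stride by default), with $C^2$ quintic/bump
   blends through swing; foot orientation is constant through dwell.
3. **Exact joint-center consistency.** The pelvis is the third root
   (progression plus bob/sway/surge oscillations and yaw/list/pitch
   angular oscillations); thigh and shank are placed by closed-form
   two-link inverse kinematics between hip and ankle at every sample, so
   all six joint-center residuals vanish identically.

Point 3 has a consequence worth stating plainly: the simulated legs are
driven by foot and pelvis trajectories with joint angles *emerging* from
inverse kinematics, not by prescribed per-joint angle waveforms. The angle
decomposition is therefore validated independently of the simulator by a
forward-compose/decompose oracle (compose a known (FE, AbAd, IE) triple,
recover it to $10^{-9}$), and the truth angle streams stored in a
`gait_truth` are the decomposition of the truth segment rotations.

The simulated knee is an **exact hinge** (thigh and shank share the leg
plane's normal as flexion axis). This is deliberate: the knee joint-axis
correction is tight, so any out-of-plane knee motion in truth would be
partly suppressed by the filter and would contaminate the noise-free
validation regime. Real knees carry a few degrees of abduction and
internal rotation; passing tests on this simulator therefore demonstrates
correct filter mechanics, not that a real knee's out-of-plane angles are
recovered to the same accuracy. Likewise the feet are planted flat through
stance (no heel-to-toe rocker), which requires the knees to stay slightly
flexed — kinematically consistent, anatomically simplified.

The mid-swing foot rotation uses two axes (pitch 22°, yaw wobble 25°) with
offset stationary points confined to a fixed ~0.55 s window, so the foot
gyroscope magnitude clearly exceeds the 60 deg/s still threshold throughout
the rotation window at every gait speed; outside it the foot translates
without rotating, which keeps one contiguous still interval per stance —
the structure the footfall detector expects, and one the accelerometer
stationarity condition then trims to the true dwell.

Anthropometry defaults: thigh 0.44 m, shank 0.43 m, mid-hip height 0.84 m,
hip half-width 0.09 m, ankle height 0.09 m, heel offset
$(-0.05, -0.07, 0)$ m in the foot anatomical frame. Pelvis oscillations:
bob 0.015 m and surge 0.02 m at step frequency, sway 0.025 m at stride
frequency, yaw/list/pitch 5/3/2°. Mounting rotations and IMU placements are
fixed non-trivial constants exported exactly in the generated
`gait_calibration`, so the filter operates with perfect calibration — real
deployments add soft-tissue artefact and calibration error on top of
everything measured here.

### What the simulator does not emulate

Gyroscope and accelerometer bias and scale-factor error (a constant gyro
bias is available as an option but defaults to zero, and the filter carries
no bias states), heel-strike impact transients, belt-speed fluctuation, and
human waveform variability. Soft-tissue motion of sensors relative to bone
(the main real-world motivation for the soft hip hinge) is available as an
option in `synthesize_imu()` — a small sinusoidal wobble of the thigh
sensors relative to their segments, perturbing the measured signals while
the filter keeps the nominal constant calibration — but defaults to off, so
the default conditions isolate sensor noise as the only error source.
Accuracy numbers obtained on this test bed are accordingly much better than
what the same pipeline achieves on human data; their role is to verify the
machinery, the geometry and the drift-correction behaviour, not to predict
clinical accuracy.

## Validation and problem sizes

The test suite validates, among other properties: all five analytic
Jacobians against central finite differences (200 random states, relative
tolerance $10^{-5}$); the strapdown round trip; covariance symmetry and
positive semidefiniteness through 10,000 fuzzed predict/update cycles; and
the end-to-end study-scale contrast on one 60 s noisy forward-walking trial
— the full filter's joint-angle RMS error beats raw integration for every
one of the 18 angle series, stays below 5° on the headline angle set
(observed ~0.4°), and stride-metric RMS errors stay below 0.13 m (observed
~0.004 m), while the aggregate prediction-only error grows quarter over
quarter and the filter's stays flat. Unit tests run on 10–20 s trials to
keep the suite fast; `scripts/acceptance.R` reproduces the 60 s headline
numbers from scratch.

## Known limitations

- No magnetometer and no bias states: global heading is unobservable and
  slowly random-walks; joint angles are unaffected (they are relative),
  but absolute world-frame heading is not meaningful over long trials.
- Internal/external rotation is the least-observed degree of freedom, as
  with all IMU-based lower-limb methods; on real data it carries the
  largest offsets.
- The filter assumes the sensor-to-segment alignment is constant and
  correct; it is consumed, not estimated.
- Single-threaded, offline (non-causal only in the final angle smoothing);
  a 60 s, 7-IMU trial filters in roughly 20 s of CPU time.
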
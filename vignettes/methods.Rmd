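---
title: "Magnetometer-free inertial-robotic arm tracking: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-free inertial-robotic arm tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armfuse)
```

## The estimation problem

A two-segment kinematic chain (forearm + upper arm) is connected to an
end-effector-based robot at the distal segment. The robot delivers the
elbow position `p_E` in its workspace frame R (z up) at 25 Hz, but nothing
about the upper arm. An IMU on the upper arm delivers body-frame angular
rate and specific force at 100 Hz. Without a magnetometer, inertial
orientation estimation can fix the inclination (from the accelerometer)
but not the heading: the filter's reference frame I shares only the
vertical axis with R and is offset by an unknown heading angle δ(t) that
drifts with the integrated gyroscope bias (typical MEMS biases
0.1–0.76 deg/s produce drifts of several tenths of a degree per second).
The package estimates δ̂ by comparing two independent measurements of the
same physical quantity — the elbow acceleration — one derived from the IMU
(expressed in I), one from twice-differentiated robot positions
(expressed in R). Rotating the former about the vertical by the correct δ
makes them agree; the best agreement over a moving window identifies δ̂.

## Orientation filter

`estimate_orientation()` is a complementary strapdown filter: per sample
the quaternion is advanced by the exact exponential of ω·dt (no Euler
step-size artifacts), then tipped toward agreement between the rotated
accelerometer direction and the vertical. The correction axis `v_I × z`
is horizontal by construction, so the heading component is provably never
corrected — heading unobservability is structural, not accidental, and
pre-rotating the initial state about z shifts every subsequent heading by
exactly that angle (a property test asserts this to 1e-6 degrees).

The correction gain (default `0.2 s⁻¹`, i.e. a ≈5 s time constant) trades
two errors: a horizontal gyro-bias component `b` leaves a steady tilt
error of about `b/gain` (≈1° at the default bias), while linear
accelerations during movement masquerade as gravity and inject tilt
ripple proportional to the gain. A substantially smaller gain
(0.01-scale) would let the default bias accumulate tens of degrees of
tilt; a larger one couples arm dynamics into the inclination. Corrections
are additionally de-weighted when the specific-force norm deviates from
9.81 m/s² and skipped entirely below half gravity (free-fall guard).
Initialization takes the tilt from the first accelerometer sample and
heading zero; any other choice is absorbed by δ. No rest phase or bias
calibration is required, and none is simulated.

## Heading-offset estimator

The elbow specific force in the body frame is
`ã_E = ã + [ω]×² p + [ω̇]× p` with `p` the IMU-to-elbow offset. The raw
rate enters the centripetal term; only `ω̇` is obtained by differentiating
the 2.5 Hz 5th-order-Butterworth-filtered rate. Because that pre-filter
delays its output by its passband group delay (≈0.2 s) while all other
signal paths are undelayed, and because the elbow-acceleration direction
rotates at roughly 78 deg/s on average along a cyclic path, an
uncompensated delay of even 30 ms biases δ̂ by over 2°. The package
therefore measures the pre-filter's group delay (phase of a filtered
probe sinusoid) and shifts the differentiated signal back into content
alignment; the newest fraction of a second of data is effectively unused,
which is immaterial for windows evaluated every 5 s. On noise-free
simulation this reduces the converged heading error from ≈2.5° to ≈0.4°,
i.e. to the 1° grid resolution.

Both acceleration signals pass identical causal 0.5 Hz 5th-order
Butterworth low-passes, so their common group delay cancels in the
disagreement `d(δ) = Rz(δ) a_E − p̈_E`. Filters are forward-only (the
method is real-time); startup transients are absorbed by constant
padding. The windowed cost `c(δ) = Σ‖d‖²` reduces algebraically to
`S0 − 2(S1 cos δ + S2 sin δ)`, which the implementation evaluates on the
grids; a brute-force rotate-and-sum oracle in the tests confirms exact
equivalence.

The 100 Hz IMU-side signal is paired with the 25 Hz robot samples by
nearest timestamp after filtering (the robot is the coarser clock; the
window length m is then 500 samples for 20 s). Updates run every 5 s of
stream time over the last 20 s, gated by motion: the window is split into
five 4 s sub-windows, a sub-window counts as moving when the elbow's
maximum pairwise excursion exceeds the 0.10 m sphere *diameter* (a
literal reading of the tolerance), and at least three of five must move.
The gate both avoids uninformative (e.g. purely vertical or static)
windows — where the cost is flat in δ — and freezes δ̂ when there is
nothing to correct.

Before convergence each gated update is two-step: coarse argmin over
{0°, 5°, …, 355°}, then 1° refinement within ±5°. Convergence is declared
once five consecutive gated estimates differ pairwise by at most 5°
(wrapped); non-gated intervals neither produce estimates nor reset the
streak. Afterwards a one-step ±5° search centered on the previous
estimate tracks the drift — at 0.5 deg/s drift and 5 s updates the
optimum moves 2.5° per update, safely inside the grid. Falling back to
the two-step update is deliberately not implemented; instead a warning is
logged whenever a one-step result lands on the grid edge. Equal-cost grid
ties are broken deterministically by the smallest wrapped angle (positive
preferred), which only matters for degenerate windows.

Before the first gated update δ̂ is undefined and every pose is flagged
invalid rather than fabricated. Between updates δ̂ is held piecewise
constant for the 100 Hz pose output; interpolation would gain at most the
intra-update drift (≤2.5°), below the method's accuracy.

## Pose, detector, biofeedback

`q_RA = Rz(δ̂) ⊗ q_IA`; the elbow angle is computed via
`atan2(‖u×v‖, u·v)` between the forearm axis (from the robot cuffs,
pointing wrist→elbow) and the upper-arm axis `x_A = (1,0,0)` rotated by
`q_RA` (pointing shoulder→elbow) — both axes point toward the joint, so
full extension reads 180°. The shoulder is the elbow minus `l_A` along
the upper-arm axis; `‖p_S − p_E‖ = l_A` holds exactly, and a 1° heading
error moves the endpoint by at most `2·l_A·sin(0.5°)` (< 1 cm for
`l_A ≤ 0.5 m`). The conventional baseline — shoulder pinned at the
nominal position, upper-arm axis from nominal shoulder to measured
elbow — is computed alongside for comparison; its shoulder error
reproduces the true displacement by construction.

A completed cycle is *compensatory* when the Euclidean displacement
`‖p_S − p_S_nom‖` exceeds 0.10 m for strictly more than 20 % of the
cycle (time-weighted over samples; exactly 20 % is tolerated, matching
"up to 20 %"). Displacement is 3-D by default with a planar option for
camera-style comparisons. Cycles containing poses before the first
heading convergence are reported unclassifiable. The three-state
indicator is green within tolerance, blue outside it, orange once the
out-of-tolerance duration exceeds a configurable maximum (default
expressed as a fraction of the cycle duration; 20 % of a ≈5 s cycle is
about one second).

## What the simulator emulates — and what it does not

`simulate_trial()` models a seated subject tracing a rounded rectangle
(0.36 × 0.20 m, C∞-smooth `tanh`-flattened ellipse, counterclockwise,
4.6 s per proper cycle and 5.4 s per compensatory cycle) on a horizontal
surface at shoulder height, solved by planar two-link inverse kinematics
(upper arm 0.30 m, forearm 0.25 m, elbow-right branch). Compensation is a
forward trunk-lean translation of the shoulder, `sin²`-shaped and
phase-locked to the cycle, with peak displacement equal to
`shoulder_amp_m` (0.04 m proper / 0.14 m compensatory). The IMU model
inverts the measurement equations: body rates from the quaternion
trajectory (central differences of the rotation log), specific force at
the sensor point (15 cm proximal of the elbow) including gravity, plus a
constant gyro bias (default magnitude 0.34 deg/s along (1,1,1)/√3) and
white noise (gyro 0.5 deg/s, accelerometer 0.05 m/s², robot positions
5 mm RMS — plausible MEMS/cable-robot values, configurable since no
sensor spec is normative). Robot samples are exact 4:1 decimations of the
100 Hz truth with added noise, including the two forearm cuffs whose
extrapolation reproduces the elbow exactly.

The simulator deliberately omits soft-tissue artifact dynamics (a
low-frequency mount-jitter hook exists but is off by default), cable
oscillations and slack-rope glitches, out-of-plane arm motion, and human
cycle-to-cycle variability. Passing tests therefore demonstrate
correctness of the algorithms under a faithful rigid-body measurement
model with realistic bias and noise — not performance on real patients;
on recorded data the same pipeline would additionally face the
disturbances above, which the original experiments put at the few-cm /
few-degree level.

## Numerical choices and degenerate inputs

Quaternions are scalar-first Hamilton; comparisons canonicalize the sign.
Angles are degrees at every interface, radians internally. Zero vectors
are rejected by `normalize_vec()` (degenerate geometry) rather than
patched; coincident cuffs, non-monotone timestamps, missing columns and
too-short windows raise errors. Elbow angles use `atan2` of cross and dot
products to avoid `acos` precision loss near 0°/180°. The window cost
uses exact sufficient statistics, so grid evaluation is O(grid) rather
than O(grid × window).

## Problem sizes

The shipped evaluation (`classification_experiment()`, also run by
`scripts/acceptance.R`) simulates 50 cycles per movement class
(≈ 8.5 min of data in total, ≈ 60 000 IMU samples), which leaves at
least 40 classifiable cycles per class after the ≈45 s heading
convergence warm-up; the full run takes a few seconds on one CPU.
Property tests use windows of 10–50 aligned samples, which is enough for
exact recovery since the construction is noise-free.

## Known limitations

* The heading is only observable while the elbow accelerates
  horizontally; long rests freeze δ̂, and the gyro bias keeps drifting
  underneath (≈0.3 deg/s × rest duration of error accrues before the
  next gated update corrects it).
* The 1° refinement grid bounds the best-case heading accuracy at 1°.
* Sensor-to-segment alignment and segment geometry are assumed known;
  the sensitivity harness (`sensitivity_sweep()`) quantifies the impact
  of IMU placement (±7.5 cm), upper-arm length (±2.5 cm — no effect on
  the elbow angle, which never uses `l_A`) and derivative-filter cutoff
  (±1 Hz) misestimates.
* The simulator's planar motion leaves the inclination channel barely
  exercised beyond noise rejection; out-of-plane validation requires
  real recordings.
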
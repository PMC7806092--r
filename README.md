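# armfuse

Magnetometer-free fusion of a single wearable IMU with the position
measurements of an end-effector-based rehabilitation robot, for real-time
tracking of the upper arm and shoulder.

## The problem

End-effector-based rehabilitation robots (e.g. cable-driven arm-weight
support systems) attach only to the forearm, so they measure the forearm
and elbow but know nothing about the upper arm or the shoulder. The common
workaround — assuming the shoulder never moves — breaks down exactly when
it matters: when a patient compensates reduced shoulder/elbow mobility by
leaning the trunk or shrugging the shoulder girdle (shoulder displacements
around 14 cm, versus about 4 cm during proper movements). An IMU strapped
to the upper arm could fill the gap, but indoor magnetic fields are too
disturbed for magnetometer-based heading estimation, and without a
magnetometer the IMU's heading drifts with the gyroscope bias.

`armfuse` implements a fusion method that needs **no magnetometer**: the
robot-measured elbow position provides the missing heading reference.

## The method

1. **Orientation filter.** A strapdown quaternion filter integrates the
   body-frame angular rate ω and corrects the inclination with the
   accelerometer. The estimate `q_IA` has accurate inclination but an
   arbitrary, slowly drifting heading: the inertial frame I and the robot
   frame R share only their vertical axis and differ by a drifting heading
   offset δ(t).
2. **Heading-offset estimation.** The accelerometer reading is translated
   to the elbow, `ã_E = ã + [ω]×² p + [ω̇]× p`, rotated into I and
   gravity-compensated: `a_E = q_IA ⊗ ã_E ⊗ q_IA* − (0,0,9.81)`. Ideally
   `Rz(δ) a_E` equals the second time derivative of the robot-measured
   elbow position `p̈_E`. Both signals are low-pass filtered (causal
   5th-order Butterworth, 0.5 Hz) and compared over a moving 20 s window:
   `c(δ) = Σ‖Rz(δ) a_E − p̈_E‖²`. Every 5 s — provided the elbow actually
   moved (at least three of five 4 s sub-windows leave a 10 cm sphere) —
   `δ̂ = argmin c(δ)` is found on a 5° grid refined to 1°; after five
   consecutive stable estimates a ±5° one-step search tracks the drift.
3. **Pose.** `q_RA = Rz(δ̂) ⊗ q_IA` gives the upper-arm orientation in
   the robot frame, the elbow angle is the angle between the forearm and
   upper-arm axes, and the shoulder is `p_S = p_E − q_RA ⊗ (l_A,0,0) ⊗
   q_RA*`.
4. **Compensation detection.** A completed motion cycle is *compensatory*
   when `‖p_S − p_S_nom‖ > 0.10 m` for more than 20 % of the cycle;
   a green/blue/orange indicator drives real-time biofeedback.

A kinematic simulator (`simulate_trial()`) generates ground-truth
two-segment arm motion — a hand tracing a rounded rectangle, with
controllable shoulder-displacement amplitude — and corrupts it into a
100 Hz IMU stream (gyro bias + noise) and a 25 Hz robot stream, so the
whole pipeline runs and is tested without hardware.

## Worked example

```r
library(armfuse)

cfg   <- trial_config(n_cycles = 20, shoulder_amp_m = 0.04, seed = 7)
trial <- simulate_trial(cfg)
res   <- track_trial(trial$imu, trial$robot, geometry_config(),
                     trial$p_S_nom)
tail(res$heading[, c("t", "delta_hat", "gated", "converged")], 3)
#>     t delta_hat gated converged
#> 13 80        13  TRUE      TRUE
#> 14 85        10  TRUE      TRUE
#> 15 90         8  TRUE      TRUE

ev <- evaluate_tracking(res$pose, trial$truth, trial$cycles)
ev$cycle_based
#>         method     metric     median          p5        p95
#> 1       hybrid shoulder_m 0.01648227 0.008311869 0.02940693
#> 2 conventional shoulder_m 0.02000000 0.020000000 0.02000000
#> 3       hybrid  elbow_deg 2.79281628 1.227671472 5.44517364
#> 4 conventional  elbow_deg 1.97950412 1.674005661 2.10666444
```

The heading log shows the estimated offset `delta_hat` (degrees) slowly
following the gyro-bias-induced drift after convergence at the fifth gated
update. The cycle-based table gives the median (and 5th/95th percentile)
over cycles of the per-cycle mean errors: the hybrid shoulder estimate is
accurate to about 2 cm here, while the conventional fixed-shoulder
baseline's error equals the actual shoulder displacement by construction
(2 cm mean for a 4 cm-amplitude trial).

Classify cycles and drive the biofeedback indicator:

```r
cyc <- trial$cycles; cyc$label <- "proper"
det <- classify_cycles(res$pose, cyc, trial$p_S_nom)
detection_confusion(det)$accuracy   # 1 on classifiable cycles
biofeedback_state(0.15, over_limit_duration_s = 0.2, max_tolerated_s = 1)
#> [1] "blue"
```

A thin command-line front end with `simulate`, `track`, `detect`,
`evaluate` and `sensitivity` subcommands is installed under
`inst/cli/armfuse.R`.

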
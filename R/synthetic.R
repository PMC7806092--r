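#' Synthetic two-segment arm trials
#'
#' Generates ground-truth cyclic arm motion emulating a seated subject
#' tracing a rectangular path on a horizontal surface with the right hand,
#' with or without compensatory shoulder displacement, and corrupts the
#' truth into the two measurement streams of the hybrid system: a 100 Hz
#' IMU stream (body-frame angular rate and specific force, with gyroscope
#' bias and white noise) and a 25 Hz robot stream (elbow and forearm-cuff
#' positions with additive noise). The motion is planar (all joints at
#' shoulder height), matching the tabletop task; compensation is modeled
#' as a forward trunk-lean translation of the shoulder phase-locked to the
#' hand cycle, with peak displacement equal to `shoulder_amp_m`
#' (0.04 m for proper movements, 0.14 m for compensatory ones).
#'
#' @name synthetic_data
NULL

#' Trial configuration for the synthetic generator
#'
#' @param n_cycles Number of motion cycles.
#' @param cycle_period_s Cycle duration (s): 4.6 for proper, 5.4 for
#'   compensatory movements.
#' @param shoulder_amp_m Peak shoulder displacement (m): 0.04 proper,
#'   0.14 compensatory.
#' @param rect_halfwidth_m,rect_halfdepth_m Half extents of the hand path
#'   rectangle (m).
#' @param rect_center_xy Rectangle center relative to the nominal shoulder,
#'   horizontal plane (m).
#' @param squareness Corner-rounding parameter of the path (larger is more
#'   rectangular).
#' @param p_S_nom Nominal shoulder position in the robot frame (m).
#' @param l_A,l_F,l_p Upper-arm length, forearm (wrist-cuff-to-elbow)
#'   length, and proximal-cuff-to-elbow distance (m).
#' @param p_imu_to_joint IMU-to-elbow offset in the upper-arm frame (m).
#' @param gyro_bias_deg_s Gyroscope bias magnitude (deg/s); default the
#'   0.34 deg/s average of typical MEMS units.
#' @param gyro_bias_axis Direction of the bias vector.
#' @param gyro_noise_sd_deg_s,acc_noise_sd,robot_pos_noise_sd White-noise
#'   standard deviations (deg/s, m/s^2, m).
#' @param imu_rate_hz,robot_rate_hz Stream rates (Hz); the IMU rate must be
#'   an integer multiple of the robot rate.
#' @param seed Random seed for reproducible streams.
#' @return Named list of class `trial_config`.
#' @export
trial_config <- function(n_cycles = 10, cycle_period_s = 4.6,
                         shoulder_amp_m = 0.04,
                         rect_halfwidth_m = 0.18, rect_halfdepth_m = 0.10,
                         rect_center_xy = c(0, 0.35), squareness = 2,
                         p_S_nom = c(0, 0, 0.9),
                         l_A = 0.30, l_F = 0.25, l_p = 0.05,
                         p_imu_to_joint = c(0.15, 0, 0),
                         gyro_bias_deg_s = 0.34,
                         gyro_bias_axis = c(1, 1, 1),
                         gyro_noise_sd_deg_s = 0.5,
                         acc_noise_sd = 0.05,
                         robot_pos_noise_sd = 0.005,
                         imu_rate_hz = 100, robot_rate_hz = 25,
                         seed = 1L) {
  stopifnot(n_cycles >= 1, cycle_period_s > 0, shoulder_amp_m >= 0,
            imu_rate_hz > 0, robot_rate_hz > 0,
            abs(imu_rate_hz / robot_rate_hz -
                  round(imu_rate_hz / robot_rate_hz)) < 1e-9,
            l_A > 0, l_F > 0, l_p >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "trial_config"
  cfg
}

# Smooth rounded-rectangle parametrization: C-infinity, flattened sides.
rounded_rect <- function(theta, a, b, lambda) {
  cbind(a * tanh(lambda * cos(theta)) / tanh(lambda),
        b * tanh(lambda * sin(theta)) / tanh(lambda))
}

#' Generate ground-truth arm motion
#'
#' Produces smooth shoulder, elbow and wrist trajectories and the upper-arm
#' orientation quaternion, sampled at the IMU rate, by planar two-link
#' inverse kinematics: the hand follows a rounded rectangle
#' counterclockwise while the shoulder translates forward with a
#' `sin^2`-shaped displacement of peak `shoulder_amp_m` once per cycle.
#'
#' @param cfg A [trial_config()].
#' @return Data frame `truth` with columns `t`, `qw..qz` (true `q_RA`),
#'   shoulder `psx/y/z`, elbow `pex/y/z`, wrist `pwx/y/z`, proximal cuff
#'   `ppx/y/z`, forearm axis `xcx/y/z`, and `elbow_deg`; plus attribute
#'   `cycles` (data frame `t_start`, `t_end`).
#' @export
generate_arm_motion <- function(cfg) {
  dt <- 1 / cfg$imu_rate_hz
  duration <- cfg$n_cycles * cfg$cycle_period_s
  t <- seq(0, duration, by = dt)
  z0 <- cfg$p_S_nom[3]

  th <- 2 * pi * t / cfg$cycle_period_s
  hand_xy <- rounded_rect(th, cfg$rect_halfwidth_m, cfg$rect_halfdepth_m,
                          cfg$squareness)
  hand_xy[, 1] <- hand_xy[, 1] + cfg$p_S_nom[1] + cfg$rect_center_xy[1]
  hand_xy[, 2] <- hand_xy[, 2] + cfg$p_S_nom[2] + cfg$rect_center_xy[2]

  disp <- cfg$shoulder_amp_m * sin(pi * t / cfg$cycle_period_s)^2
  S <- matrix(c(rep(cfg$p_S_nom[1], length(t)),
                cfg$p_S_nom[2] + disp, rep(z0, length(t))), ncol = 3)

  dx <- hand_xy[, 1] - S[, 1]
  dy <- hand_xy[, 2] - S[, 2]
  d <- sqrt(dx^2 + dy^2)
  if (any(d >= cfg$l_A + cfg$l_F - 1e-3) ||
      any(d <= abs(cfg$l_A - cfg$l_F) + 1e-3))
    stop("hand path unreachable for the given segment lengths")
  psi <- atan2(dy, dx)
  alpha <- acos(pmin(1, pmax(-1, (cfg$l_A^2 + d^2 - cfg$l_F^2) /
                               (2 * cfg$l_A * d))))
  phi_A <- psi - alpha  # elbow-right solution for a right arm

  E <- cbind(S[, 1] + cfg$l_A * cos(phi_A),
             S[, 2] + cfg$l_A * sin(phi_A), z0)
  W <- cbind(hand_xy, z0)
  u <- (E - W) / sqrt(rowSums((E - W)^2))  # forearm axis, wrist -> elbow
  P <- E - cfg$l_p * u

  h <- phi_A / 2
  Q <- cbind(cos(h), 0, 0, sin(h))

  xa <- cbind(cos(phi_A), sin(phi_A), 0)
  cv <- cbind(u[, 2] * xa[, 3] - u[, 3] * xa[, 2],
              u[, 3] * xa[, 1] - u[, 1] * xa[, 3],
              u[, 1] * xa[, 2] - u[, 2] * xa[, 1])
  elb <- rad2deg(atan2(sqrt(rowSums(cv^2)), rowSums(u * xa)))

  truth <- data.frame(t = t, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3],
                      qz = Q[, 4],
                      psx = S[, 1], psy = S[, 2], psz = S[, 3],
                      pex = E[, 1], pey = E[, 2], pez = E[, 3],
                      pwx = W[, 1], pwy = W[, 2], pwz = W[, 3],
                      ppx = P[, 1], ppy = P[, 2], ppz = P[, 3],
                      xcx = u[, 1], xcy = u[, 2], xcz = u[, 3],
                      elbow_deg = elb)
  attr(truth, "cycles") <- data.frame(
    t_start = (seq_len(cfg$n_cycles) - 1) * cfg$cycle_period_s,
    t_end = seq_len(cfg$n_cycles) * cfg$cycle_period_s)
  truth
}

# Body-frame angular velocity from a quaternion trajectory by central
# differences of the relative-rotation log map.
quat_angular_velocity <- function(Q, dt) {
  n <- nrow(Q)
  W <- matrix(0, n, 3)
  for (k in 2:(n - 1)) {
    dq <- quat_multiply(quat_conjugate(Q[k - 1, ]), Q[k + 1, ])
    if (dq[1] < 0) dq <- -dq
    s <- sqrt(sum(dq[2:4]^2))
    ang <- 2 * atan2(s, dq[1])
    W[k, ] <- if (s > 1e-12) ang * dq[2:4] / s / (2 * dt) else c(0, 0, 0)
  }
  W[1, ] <- W[2, ]
  W[n, ] <- W[n - 1, ]
  W
}

#' Simulate the IMU measurement stream
#'
#' Inverts the measurement model: the gyroscope reads the body-frame
#' angular velocity of the true orientation plus bias and white noise; the
#' accelerometer reads the body-frame specific force at the sensor
#' location (the elbow minus the IMU-to-joint offset) plus white noise.
#'
#' @param truth Ground truth from [generate_arm_motion()].
#' @param cfg The [trial_config()].
#' @param g Gravitational acceleration (m/s^2).
#' @return Data frame `t, gx, gy, gz, ax, ay, az`.
#' @export
simulate_imu <- function(truth, cfg, g = 9.81) {
  dt <- 1 / cfg$imu_rate_hz
  n <- nrow(truth)
  Q <- cbind(truth$qw, truth$qx, truth$qy, truth$qz)
  W <- quat_angular_velocity(Q, dt)

  # sensor point on the segment and its acceleration
  off <- quat_rotate_rows(Q, matrix(rep(cfg$p_imu_to_joint, each = n),
                                    ncol = 3))
  Pimu <- cbind(truth$pex, truth$pey, truth$pez) - off
  A <- matrix(0, n, 3)
  A[2:(n - 1), ] <- (Pimu[3:n, ] - 2 * Pimu[2:(n - 1), ] + Pimu[1:(n - 2), ]) / dt^2
  A[1, ] <- A[2, ]
  A[n, ] <- A[n - 1, ]
  A[, 3] <- A[, 3] + g  # specific force in the world frame

  # express in body frame: q* (x) v (x) q
  Qc <- cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
  acc_body <- quat_rotate_rows(Qc, A)

  bias <- deg2rad(cfg$gyro_bias_deg_s) * normalize_vec(cfg$gyro_bias_axis)
  gyro <- W + matrix(rep(bias, each = n), ncol = 3) +
    matrix(stats::rnorm(3 * n, sd = deg2rad(cfg$gyro_noise_sd_deg_s)), n, 3)
  acc <- acc_body + matrix(stats::rnorm(3 * n, sd = cfg$acc_noise_sd), n, 3)

  data.frame(t = truth$t, gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
             ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
}

#' Simulate the robot measurement stream
#'
#' Downsamples the true elbow and cuff positions to the robot rate and adds
#' white position noise.
#'
#' @param truth Ground truth from [generate_arm_motion()].
#' @param cfg The [trial_config()].
#' @return Data frame `t, pex, pey, pez, pwx, pwy, pwz, ppx, ppy, ppz`.
#' @export
simulate_robot <- function(truth, cfg) {
  step <- as.integer(round(cfg$imu_rate_hz / cfg$robot_rate_hz))
  idx <- seq(1, nrow(truth), by = step)
  cols <- c("pex", "pey", "pez", "pwx", "pwy", "pwz", "ppx", "ppy", "ppz")
  out <- truth[idx, c("t", cols)]
  noise <- matrix(stats::rnorm(length(idx) * length(cols),
                               sd = cfg$robot_pos_noise_sd),
                  nrow = length(idx))
  out[cols] <- out[cols] + noise
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic trial
#'
#' Seeds the random generator from `cfg$seed`, generates ground truth and
#' both measurement streams, and bundles them with the cycle boundaries.
#'
#' @param cfg A [trial_config()].
#' @param g Gravitational acceleration (m/s^2).
#' @return List of class `synthetic_trial`: `truth`, `imu`, `robot`,
#'   `cycles`, `p_S_nom`, `config`.
#' @export
simulate_trial <- function(cfg, g = 9.81) {
  set.seed(cfg$seed)
  truth <- generate_arm_motion(cfg)
  imu <- simulate_imu(truth, cfg, g = g)
  robot <- simulate_robot(truth, cfg)
  structure(list(truth = truth, imu = imu, robot = robot,
                 cycles = attr(truth, "cycles"),
                 p_S_nom = cfg$p_S_nom, config = cfg),
            class = "synthetic_trial")
}
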
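#' Magnetometer-free strapdown orientation filter
#'
#' Estimates the IMU orientation `q_IA` with respect to an inertial frame
#' whose z-axis is vertical and whose heading is arbitrary and free to
#' drift. Each sample advances the quaternion by exact exponential
#' integration of the body-frame angular rate and then applies a small
#' accelerometer-based inclination correction about a horizontal axis.
#' Because the correction axis is always horizontal, the heading component
#' is never corrected: no magnetometer is used, and heading drift caused by
#' gyroscope bias is left for the heading-offset estimator to absorb.
#'
#' @name orientation_filter
NULL

#' Initialize the orientation state from the first accelerometer sample
#'
#' The initial quaternion is the pure-tilt rotation aligning the measured
#' specific-force direction with the vertical; the initial heading is zero
#' (any constant choice is absorbed by the heading offset).
#'
#' @param acc First accelerometer sample (specific force, m/s^2, body frame).
#' @param t Timestamp of the first sample (s).
#' @return An orientation state list with elements `q` and `t_last`.
#' @export
orientation_init <- function(acc, t = 0) {
  n <- sqrt(sum(acc^2))
  if (n < 1e-6) {
    q <- quat_identity()
  } else {
    u <- acc / n
    z <- c(0, 0, 1)
    ax <- cross3(u, z)
    s <- sqrt(sum(ax^2))
    if (s < 1e-12) {
      q <- if (u[3] > 0) quat_identity() else quat(0, 1, 0, 0)
    } else {
      ang <- atan2(s, sum(u * z))
      q <- quat_from_axis_angle(ax, ang)
    }
  }
  list(q = q, t_last = t)
}

#' Advance the orientation filter by one IMU sample
#'
#' @param state Orientation state from [orientation_init()] or a previous
#'   update.
#' @param t Sample timestamp (s); must exceed `state$t_last`.
#' @param gyro Angular rate, rad/s, body frame.
#' @param acc Specific force, m/s^2, body frame.
#' @param gain Inclination correction gain in 1/s. The steady-state tilt
#'   error under a horizontal gyro bias `b` is about `b / gain`.
#' @param g Gravitational acceleration (m/s^2).
#' @return Updated orientation state.
#' @export
orientation_update <- function(state, t, gyro, acc, gain = 0.2, g = 9.81) {
  dt <- t - state$t_last
  if (dt <= 0) stop("orientation_update: non-monotone timestamps")
  q <- state$q
  # strapdown step: exact exponential of the body rate over dt
  ang <- sqrt(sum(gyro^2)) * dt
  if (ang > 0) {
    q <- quat_multiply(q, quat_from_axis_angle(gyro, ang))
  }
  # inclination correction: rotate the estimate so the measured specific
  # force, expressed in I, tips toward vertical; the correction axis
  # v_I x z has zero z-component, so the heading is never touched.
  an <- sqrt(sum(acc^2))
  if (an > 0.5 * g) {  # free-fall / low-|a| guard
    v_i <- quat_rotate(q, acc / an, tol = 1e-3)
    ax <- c(v_i[2], -v_i[1], 0)      # v_i x z
    s <- sqrt(sum(ax^2))
    if (s > 1e-12) {
      tilt_err <- atan2(s, v_i[3])
      w <- max(0, 1 - abs(an - g) / (0.3 * g))  # de-weight dynamic phases
      corr <- min(gain * w * dt, 1) * tilt_err
      q <- quat_multiply(quat_from_axis_angle(ax, corr), q)
    }
  }
  list(q = quat_normalize(q), t_last = t)
}

#' Run the orientation filter over a full IMU stream
#'
#' @param imu Data frame with columns `t`, `gx`, `gy`, `gz` (rad/s) and
#'   `ax`, `ay`, `az` (m/s^2), timestamps strictly increasing.
#' @param gain Inclination correction gain (1/s).
#' @param g Gravitational acceleration (m/s^2).
#' @param q0 Optional initial quaternion; default from the first
#'   accelerometer sample.
#' @return n x 4 matrix of unit quaternions `q_IA` (columns w, x, y, z),
#'   one row per IMU sample.
#' @export
estimate_orientation <- function(imu, gain = 0.2, g = 9.81, q0 = NULL) {
  tt <- imu$t
  if (any(diff(tt) <= 0)) stop("IMU timestamps must be strictly increasing")
  G <- cbind(imu$gx, imu$gy, imu$gz)
  A <- cbind(imu$ax, imu$ay, imu$az)
  n <- length(tt)
  Q <- matrix(0, n, 4)
  st <- orientation_init(A[1, ], t = tt[1])
  if (!is.null(q0)) st$q <- quat_normalize(q0)
  Q[1, ] <- st$q
  if (n > 1) {
    for (k in 2:n) {
      st <- orientation_update(st, tt[k], G[k, ], A[k, ], gain = gain, g = g)
      Q[k, ] <- st$q
    }
  }
  colnames(Q) <- c("qw", "qx", "qy", "qz")
  Q
}

#' Inclination angle of an orientation estimate
#'
#' Angle in degrees between the body z-axis expressed in the reference
#' frame and the vertical; a heading-independent accuracy measure.
#'
#' @param Q n x 4 quaternion matrix (or a single quaternion).
#' @export
inclination_deg <- function(Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  z_i <- quat_rotate_rows(Q, matrix(rep(c(0, 0, 1), each = nrow(Q)), ncol = 3))
  rad2deg(acos(pmin(1, pmax(-1, z_i[, 3]))))
}
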
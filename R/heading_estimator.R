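#' Estimation of the drifting heading offset between inertial and robot frames
#'
#' The orientation filter's inertial reference frame I shares its vertical
#' axis with the robot workspace frame R but has an unknown, slowly drifting
#' heading offset `delta`. The offset is estimated by matching the
#' IMU-derived joint (elbow) acceleration, expressed in I, against the
#' second time derivative of the robot-measured joint position in R:
#' rotating the former about the vertical by the correct `delta` makes the
#' two agree. A windowed sum-of-squares cost is minimized over a coarse 5°
#' grid followed by a 1° refinement; once five consecutive estimates are
#' stable within 5°, a one-step update on a +/-5° grid tracks the drift.
#'
#' @name heading_estimator
NULL

#' Specific force at the joint from IMU quantities
#'
#' Translates the accelerometer reading from the sensor location to the
#' joint by adding the radial (centripetal) and tangential terms of the
#' rotation about the joint:
#' `sf_E = acc + [w]_x^2 p + [wdot]_x p`, all in the body frame A.
#'
#' @param acc Specific force at the sensor (m/s^2, frame A).
#' @param gyro Angular rate (rad/s, frame A).
#' @param gyro_dot Angular acceleration (rad/s^2, frame A).
#' @param p_imu_to_joint Vector from sensor to joint (m, frame A).
#' @return Specific force at the joint (m/s^2, frame A).
#' @export
joint_specific_force <- function(acc, gyro, gyro_dot, p_imu_to_joint) {
  p <- p_imu_to_joint
  acc + cross3(gyro, cross3(gyro, p)) + cross3(gyro_dot, p)
}

# Vectorized version: ACC, G, GD are n x 3; p is length 3.
joint_specific_force_rows <- function(ACC, G, GD, p) {
  P <- matrix(rep(p, each = nrow(ACC)), ncol = 3)
  wxp <- cbind(G[, 2] * P[, 3] - G[, 3] * P[, 2],
               G[, 3] * P[, 1] - G[, 1] * P[, 3],
               G[, 1] * P[, 2] - G[, 2] * P[, 1])
  wxwxp <- cbind(G[, 2] * wxp[, 3] - G[, 3] * wxp[, 2],
                 G[, 3] * wxp[, 1] - G[, 1] * wxp[, 3],
                 G[, 1] * wxp[, 2] - G[, 2] * wxp[, 1])
  wdxp <- cbind(GD[, 2] * P[, 3] - GD[, 3] * P[, 2],
                GD[, 3] * P[, 1] - GD[, 1] * P[, 3],
                GD[, 1] * P[, 2] - GD[, 2] * P[, 1])
  ACC + wxwxp + wdxp
}

#' Joint acceleration in the inertial reference frame
#'
#' Rotates the joint specific force into frame I and removes gravity:
#' `a_E = q (x) sf (x) q* - (0, 0, g)`.
#'
#' @param sf_joint Joint specific force (m/s^2, frame A).
#' @param q Unit quaternion `q_IA`.
#' @param g Gravitational acceleration (m/s^2).
#' @export
joint_acceleration_inertial <- function(sf_joint, q, g = 9.81) {
  quat_rotate(q, sf_joint) - c(0, 0, g)
}

#' Disagreement between rotated inertial and robot joint accelerations
#'
#' `d(delta) = Rz(delta) a_I - pdd_R` as a 3-vector; the cost squares its
#' norm.
#'
#' @param delta_deg Candidate heading offset in degrees.
#' @param a_I Joint acceleration in frame I (filtered, m/s^2).
#' @param pdd_R Second derivative of the robot-measured joint position
#'   (filtered, m/s^2).
#' @export
disagreement <- function(delta_deg, a_I, pdd_R) {
  quat_rotate(heading_quat(delta_deg), a_I) - pdd_R
}

#' Windowed heading cost
#'
#' Sum over the window of squared disagreement norms,
#' `c(delta) = sum_k ||Rz(delta) a_I(k) - pdd_R(k)||^2`. Because `Rz` only
#' mixes the horizontal components, the cost reduces to
#' `S0 - 2 (S1 cos d + S2 sin d)` with window sums S0, S1, S2, which this
#' implementation evaluates; it is algebraically identical to the direct
#' rotate-and-sum form.
#'
#' @param delta_deg Vector of candidate heading offsets (degrees).
#' @param a_I m x 3 matrix of inertial-frame joint accelerations.
#' @param pdd_R m x 3 matrix of robot-frame joint position second
#'   derivatives, time-aligned with `a_I`.
#' @return Numeric vector of costs, one per candidate.
#' @export
heading_cost <- function(delta_deg, a_I, pdd_R) {
  a_I <- as.matrix(a_I); pdd_R <- as.matrix(pdd_R)
  if (nrow(a_I) == 0 || nrow(a_I) != nrow(pdd_R))
    stop("heading_cost: window must hold equally many aligned pairs")
  s0 <- sum(a_I^2) + sum(pdd_R^2) - 2 * sum(pdd_R[, 3] * a_I[, 3])
  s1 <- sum(pdd_R[, 1] * a_I[, 1] + pdd_R[, 2] * a_I[, 2])
  s2 <- sum(pdd_R[, 2] * a_I[, 1] - pdd_R[, 1] * a_I[, 2])
  d <- deg2rad(delta_deg)
  s0 - 2 * (s1 * cos(d) + s2 * sin(d))
}

#' Grid minimizer of the heading cost
#'
#' Returns the grid angle minimizing [heading_cost()] over the window.
#' Ties (within machine tolerance) are broken deterministically by the
#' smallest wrapped angle.
#'
#' @param grid_deg Nonempty vector of candidate angles (degrees).
#' @param a_I,pdd_R Aligned window matrices as in [heading_cost()].
#' @return The minimizing angle, wrapped into `[0, 360)`.
#' @export
optdelta <- function(grid_deg, a_I, pdd_R) {
  if (length(grid_deg) == 0) stop("optdelta: empty grid")
  cost <- heading_cost(grid_deg, a_I, pdd_R)
  tol <- max(1e-12, 1e-12 * max(abs(cost)))
  cand <- which(cost <= min(cost) + tol)
  if (length(cand) > 1) {
    w <- wrap_angle(grid_deg[cand])
    cand <- cand[order(abs(w), -w)]
  }
  wrap_360(grid_deg[cand[1]])
}

#' Motion gate on a 20 s window of joint positions
#'
#' Splits the window into `n_sub` equal sub-windows and declares
#' considerable motion in a sub-window when the joint position does not
#' stay within a sphere of `diameter_m` diameter (max pairwise distance
#' exceeds the diameter). The window passes the gate when at least
#' `min_active` sub-windows contain considerable motion.
#'
#' @param p_E m x 3 matrix of joint positions over the window.
#' @param n_sub Number of sub-windows.
#' @param diameter_m Sphere diameter (m).
#' @param min_active Minimum number of moving sub-windows.
#' @return Logical.
#' @export
motion_gate <- function(p_E, n_sub = 5, diameter_m = 0.10, min_active = 3) {
  p_E <- as.matrix(p_E)
  m <- nrow(p_E)
  if (m < n_sub) stop("motion_gate: window shorter than the sub-window split")
  idx <- split(seq_len(m), cut(seq_len(m), n_sub, labels = FALSE))
  active <- vapply(idx, function(i) {
    if (length(i) < 2) return(FALSE)
    max(stats::dist(p_E[i, , drop = FALSE])) > diameter_m
  }, logical(1))
  sum(active) >= min_active
}

#' Create an empty heading-estimator state
#'
#' The offset estimate starts undefined; pose outputs are invalid until the
#' first gated update produces an estimate.
#'
#' @export
heading_state <- function() {
  list(delta_hat = NA_real_, converged = FALSE,
       history = numeric(0), history_t = numeric(0),
       edge_warnings = 0L)
}

#' One periodic heading update
#'
#' Called every update period (5 s of stream time) with the aligned
#' acceleration window. If the window fails the motion gate the state is
#' unchanged. Before convergence, a two-step update runs a coarse 5° grid
#' over the full circle followed by a 1° refinement within +/-5° of the
#' coarse optimum. Convergence is declared once the last five gated
#' estimates each differ by at most `conv_tol_deg` (wrapped) from their
#' predecessor; thereafter a one-step update searches a 1° grid within
#' +/-5° of the previous estimate.
#'
#' @param state Heading state from [heading_state()] or a previous update.
#' @param a_I,pdd_R Aligned window matrices (see [heading_cost()]).
#' @param gated Result of [motion_gate()] for this window.
#' @param t Stream time of the update (s).
#' @param coarse_step_deg,refine_halfwidth_deg,refine_step_deg Grid
#'   parameters (degrees).
#' @param conv_len,conv_tol_deg Convergence rule: `conv_len` consecutive
#'   estimates within `conv_tol_deg`.
#' @return Updated state; `$delta_hat` holds the newest estimate (degrees,
#'   `[0, 360)`), `$delta_tilde` the coarse estimate of a two-step update.
#' @export
update_heading <- function(state, a_I, pdd_R, gated, t,
                           coarse_step_deg = 5, refine_halfwidth_deg = 5,
                           refine_step_deg = 1, conv_len = 5,
                           conv_tol_deg = 5) {
  state$delta_tilde <- NA_real_
  if (!gated) return(state)
  if (!state$converged) {
    d_t <- optdelta(seq(0, 360 - coarse_step_deg, by = coarse_step_deg),
                    a_I, pdd_R)
    grid <- d_t + seq(-refine_halfwidth_deg, refine_halfwidth_deg,
                      by = refine_step_deg)
    d_h <- optdelta(grid, a_I, pdd_R)
    state$delta_tilde <- d_t
  } else {
    grid <- state$delta_hat + seq(-refine_halfwidth_deg,
                                  refine_halfwidth_deg, by = refine_step_deg)
    d_h <- optdelta(grid, a_I, pdd_R)
    if (abs(wrap_angle(d_h - state$delta_hat)) >= refine_halfwidth_deg - 1e-9)
      state$edge_warnings <- state$edge_warnings + 1L
  }
  state$delta_hat <- d_h
  state$history <- c(state$history, d_h)
  state$history_t <- c(state$history_t, t)
  if (!state$converged && length(state$history) >= conv_len) {
    last <- utils::tail(state$history, conv_len)
    if (all(abs(wrap_angle(diff(last))) <= conv_tol_deg))
      state$converged <- TRUE
  }
  state
}

#' Run the heading estimator over full measurement streams
#'
#' Builds the filtered, time-aligned acceleration pair from the IMU stream
#' (with its orientation estimates) and the robot joint-position stream,
#' then performs the periodic gated grid updates.
#'
#' @param imu IMU data frame (`t, gx, gy, gz, ax, ay, az`), ~100 Hz.
#' @param robot Robot data frame (`t, pex, pey, pez`), ~25 Hz.
#' @param Q n x 4 quaternion matrix from [estimate_orientation()], aligned
#'   row-wise with `imu`.
#' @param geometry List with `p_imu_to_joint` (length-3, m).
#' @param control List of algorithm constants from [run_config()].
#' @return List with `log` (data frame: one row per update with `t`,
#'   `delta_tilde`, `delta_hat`, `gated`, `converged`, `cost_min`),
#'   `state` (final heading state), and `aligned` (robot-rate data frame
#'   of the filtered acceleration pairs used in the windows).
#' @export
estimate_heading <- function(imu, robot, Q, geometry, control = run_config()) {
  fs_imu <- 1 / stats::median(diff(imu$t))
  fs_rob <- 1 / stats::median(diff(robot$t))
  ctrl <- control

  G <- cbind(imu$gx, imu$gy, imu$gz)
  ACC <- cbind(imu$ax, imu$ay, imu$az)
  GD <- gyro_derivative(G, fs_imu, ctrl$lp_cutoff_gyro, ctrl$butterworth_order)
  # content-align the differentiated (pre-filtered) rate with the raw
  # channels by compensating the pre-filter's passband group delay;
  # effectively the newest fraction of a second of data is left unused
  L <- butter_group_delay_samples(ctrl$lp_cutoff_gyro, fs_imu,
                                  ctrl$butterworth_order)
  GD <- GD[pmin(seq_len(nrow(GD)) + L, nrow(GD)), , drop = FALSE]
  SF <- joint_specific_force_rows(ACC, G, GD, geometry$p_imu_to_joint)
  AI <- quat_rotate_rows(Q, SF)
  AI[, 3] <- AI[, 3] - ctrl$gravity
  AIf <- smooth_for_disagreement(AI, fs_imu, ctrl$lp_cutoff_accel,
                                 ctrl$butterworth_order)

  PE <- cbind(robot$pex, robot$pey, robot$pez)
  PDD <- robot_joint_accel(PE, fs_rob)
  PDDf <- smooth_for_disagreement(PDD, fs_rob, ctrl$lp_cutoff_accel,
                                  ctrl$butterworth_order)

  # nearest IMU sample for each robot sample (the robot is the coarser clock)
  near <- findInterval(robot$t, imu$t + stats::median(diff(imu$t)) / 2) + 1L
  near <- pmin(pmax(near, 1L), nrow(AIf))
  AI_r <- AIf[near, , drop = FALSE]

  t0 <- robot$t[1]
  t_end <- robot$t[length(robot$t)]
  update_times <- if (t_end >= t0 + ctrl$window_s) {
    seq(t0 + ctrl$window_s, t_end, by = ctrl$update_period_s)
  } else numeric(0)  # stream shorter than one window: no updates possible
  st <- heading_state()
  log <- vector("list", length(update_times))
  for (i in seq_along(update_times)) {
    tu <- update_times[i]
    in_win <- robot$t > tu - ctrl$window_s & robot$t <= tu
    gate <- motion_gate(PE[in_win, , drop = FALSE],
                        n_sub = ctrl$n_subwindows,
                        diameter_m = ctrl$motion_sphere_m,
                        min_active = ctrl$min_active_subwindows)
    st <- update_heading(st, AI_r[in_win, , drop = FALSE],
                         PDDf[in_win, , drop = FALSE], gate, tu,
                         coarse_step_deg = ctrl$coarse_grid_step_deg,
                         refine_halfwidth_deg = ctrl$refine_halfwidth_deg,
                         refine_step_deg = ctrl$refine_step_deg,
                         conv_len = ctrl$convergence_len,
                         conv_tol_deg = ctrl$convergence_tol_deg)
    cmin <- if (gate) heading_cost(st$delta_hat, AI_r[in_win, , drop = FALSE],
                                   PDDf[in_win, , drop = FALSE]) else NA_real_
    log[[i]] <- data.frame(t = tu,
                           delta_tilde = if (gate) st$delta_tilde else NA_real_,
                           delta_hat = st$delta_hat, gated = gate,
                           converged = st$converged, cost_min = cmin)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(t = numeric(0), delta_tilde = numeric(0),
               delta_hat = numeric(0), gated = logical(0),
               converged = logical(0), cost_min = numeric(0))
  if (nrow(log) > 0 && st$edge_warnings > 0)
    warning(sprintf("one-step heading update hit the refinement grid edge %d time(s)",
                    st$edge_warnings))
  aligned <- data.frame(t = robot$t,
                        aix = AI_r[, 1], aiy = AI_r[, 2], aiz = AI_r[, 3],
                        pddx = PDDf[, 1], pddy = PDDf[, 2], pddz = PDDf[, 3])
  list(log = log, state = st, aligned = aligned)
}

#' Heading offset as a step function of time
#'
#' Piecewise-constant hold of the estimate between the periodic updates.
#'
#' @param log Update log from [estimate_heading()].
#' @param t Times at which to evaluate (s).
#' @return List with `delta_deg` (NA before the first estimate) and
#'   logical `converged` at each time.
#' @export
heading_at <- function(log, t) {
  if (is.null(log) || nrow(log) == 0) {
    return(list(delta_deg = rep(NA_real_, length(t)),
                converged = rep(FALSE, length(t))))
  }
  idx <- findInterval(t, log$t)
  delta <- ifelse(idx >= 1, log$delta_hat[pmax(idx, 1)], NA_real_)
  conv <- ifelse(idx >= 1, log$converged[pmax(idx, 1)], FALSE)
  list(delta_deg = delta, converged = conv & !is.na(delta))
}
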
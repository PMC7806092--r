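#' Segment pose reconstruction in the robot frame
#'
#' Once the heading offset is available, the upper-arm orientation in the
#' robot workspace frame follows as `q_RA = Rz(delta_hat) (x) q_IA`; the
#' elbow flexion angle is the angle between the longitudinal axes of the
#' two segments, and the shoulder position is obtained by walking back
#' along the upper-arm axis from the robot-measured elbow. Both
#' longitudinal axes point toward the elbow joint, so a fully extended arm
#' reads an elbow angle of 180 degrees.
#'
#' @name pose_reconstruction
NULL

#' Elbow position extrapolated from the two forearm cuffs
#'
#' `p_E = l_p * normalize(p_P - p_W) + p_P`: extend the line from the wrist
#' cuff through the proximal cuff by the cuff-to-elbow distance.
#'
#' @param p_W Wrist-cuff position (m, robot frame).
#' @param p_P Proximal-cuff position (m, robot frame).
#' @param l_p Distance from the proximal cuff to the elbow (m).
#' @export
elbow_from_cuffs <- function(p_W, p_P, l_p) {
  d <- p_P - p_W
  if (sqrt(sum(d^2)) < 1e-9) stop("elbow_from_cuffs: coincident cuff positions")
  l_p * normalize_vec(d) + p_P
}

#' Segment orientation in the robot frame
#'
#' @param q_IA Unit quaternion from the orientation filter.
#' @param delta_hat_deg Estimated heading offset (degrees); `NA` signals
#'   that no estimate exists yet.
#' @return `q_RA`, or an error if the offset is undefined.
#' @export
segment_orientation_R <- function(q_IA, delta_hat_deg) {
  if (is.na(delta_hat_deg))
    stop("segment_orientation_R: heading offset not yet estimated")
  quat_multiply(heading_quat(delta_hat_deg), q_IA)
}

#' Elbow angle between the two segment axes
#'
#' Angle between the forearm longitudinal axis `x_C` (robot frame, pointing
#' toward the elbow) and the upper-arm axis `x_A = (1,0,0)` rotated by
#' `q_RA`. Computed via `atan2(||cross||, dot)` for stability near 0 and
#' 180 degrees.
#'
#' @param x_C Unit forearm axis in the robot frame.
#' @param q_RA Upper-arm orientation in the robot frame.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
elbow_angle <- function(x_C, q_RA) {
  x_A <- quat_rotate(q_RA, c(1, 0, 0))
  rad2deg(atan2(sqrt(sum(cross3(x_C, x_A)^2)), sum(x_C * x_A)))
}

#' Shoulder position from elbow position and upper-arm orientation
#'
#' `p_S = p_E - q_RA (x) (l_A, 0, 0) (x) q_RA*`.
#'
#' @param p_E Elbow position (m, robot frame).
#' @param q_RA Upper-arm orientation in the robot frame.
#' @param l_A Upper-arm length (m).
#' @export
shoulder_position <- function(p_E, q_RA, l_A) {
  if (l_A <= 0) stop("shoulder_position: segment length must be positive")
  p_E - quat_rotate(q_RA, c(l_A, 0, 0))
}

#' Conventional fixed-shoulder baseline pose
#'
#' The non-augmented robot assumes the shoulder never leaves its nominal
#' position; the upper-arm axis is then the normalized vector from the
#' nominal shoulder to the measured elbow, and the elbow angle is the angle
#' between that axis and the forearm axis.
#'
#' @param p_E Elbow position (m, robot frame).
#' @param p_S_nom Nominal shoulder position (m, robot frame).
#' @param x_C Unit forearm axis (robot frame).
#' @return List with `p_S` (always `p_S_nom`) and `elbow_deg`.
#' @export
conventional_pose <- function(p_E, p_S_nom, x_C) {
  d <- p_E - p_S_nom
  if (sqrt(sum(d^2)) < 1e-9)
    stop("conventional_pose: elbow coincides with the nominal shoulder")
  x_A <- normalize_vec(d)
  ang <- rad2deg(atan2(sqrt(sum(cross3(x_C, x_A)^2)), sum(x_C * x_A)))
  list(p_S = p_S_nom, elbow_deg = ang)
}

#' Reconstruct pose time series for the hybrid and conventional methods
#'
#' Emits poses at the IMU rate. Robot-measured quantities (elbow position,
#' forearm axis) are linearly interpolated to the IMU timestamps; the
#' heading estimate is held piecewise constant between its periodic
#' updates. Poses are flagged invalid while the heading offset is still
#' undefined.
#'
#' @param imu IMU data frame (defines the output time base).
#' @param Q n x 4 quaternion matrix from [estimate_orientation()].
#' @param robot Robot data frame with `pex, pey, pez` and (optionally)
#'   forearm-axis columns `xcx, xcy, xcz` or cuff columns
#'   `pwx, pwy, pwz, ppx, ppy, ppz`.
#' @param heading_log Update log from [estimate_heading()].
#' @param geometry List with `l_A` (m) and optionally `l_p` (m).
#' @param p_S_nom Nominal shoulder position (m, robot frame).
#' @return Data frame with one row per IMU sample and columns `t`,
#'   `qw..qz` (hybrid `q_RA`), `elbow_deg`, `psx, psy, psz`,
#'   `elbow_conv_deg`, `ps_conv_x/y/z`, `delta_deg`, `valid`, `converged`.
#' @export
reconstruct_pose <- function(imu, Q, robot, heading_log, geometry, p_S_nom) {
  tt <- imu$t
  interp <- function(col) stats::approx(robot$t, robot[[col]], xout = tt,
                                        rule = 2)$y
  PE <- cbind(interp("pex"), interp("pey"), interp("pez"))
  if (all(c("xcx", "xcy", "xcz") %in% names(robot))) {
    XC <- cbind(interp("xcx"), interp("xcy"), interp("xcz"))
  } else if (all(c("pwx", "ppx") %in% names(robot))) {
    XC <- cbind(interp("ppx") - interp("pwx"),
                interp("ppy") - interp("pwy"),
                interp("ppz") - interp("pwz"))
  } else {
    stop("robot stream must carry a forearm axis or cuff positions")
  }
  XC <- XC / sqrt(rowSums(XC^2))

  h <- heading_at(heading_log, tt)
  valid <- !is.na(h$delta_deg)
  n <- length(tt)
  QRA <- matrix(NA_real_, n, 4)
  hq <- cbind(cos(deg2rad(h$delta_deg) / 2), 0, 0,
              sin(deg2rad(h$delta_deg) / 2))
  for (k in which(valid)) QRA[k, ] <- quat_multiply(hq[k, ], Q[k, ])

  XA <- matrix(NA_real_, n, 3)
  XA[valid, ] <- quat_rotate_rows(QRA[valid, , drop = FALSE],
                                  matrix(rep(c(1, 0, 0), each = sum(valid)),
                                         ncol = 3))
  elb <- rep(NA_real_, n)
  cr <- function(A, B) cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
                             A[, 3] * B[, 1] - A[, 1] * B[, 3],
                             A[, 1] * B[, 2] - A[, 2] * B[, 1])
  cv <- cr(XC[valid, , drop = FALSE], XA[valid, , drop = FALSE])
  elb[valid] <- rad2deg(atan2(sqrt(rowSums(cv^2)),
                              rowSums(XC[valid, , drop = FALSE] *
                                        XA[valid, , drop = FALSE])))
  PS <- matrix(NA_real_, n, 3)
  PS[valid, ] <- PE[valid, , drop = FALSE] - geometry$l_A * XA[valid, , drop = FALSE]

  # conventional baseline: fixed shoulder, axis from nominal shoulder to elbow
  DA <- PE - matrix(rep(p_S_nom, each = n), ncol = 3)
  DA <- DA / sqrt(rowSums(DA^2))
  cc <- cr(XC, DA)
  elb_conv <- rad2deg(atan2(sqrt(rowSums(cc^2)), rowSums(XC * DA)))

  data.frame(t = tt, qw = QRA[, 1], qx = QRA[, 2], qy = QRA[, 3],
             qz = QRA[, 4], elbow_deg = elb,
             psx = PS[, 1], psy = PS[, 2], psz = PS[, 3],
             elbow_conv_deg = elb_conv,
             ps_conv_x = p_S_nom[1], ps_conv_y = p_S_nom[2],
             ps_conv_z = p_S_nom[3],
             delta_deg = h$delta_deg, valid = valid, converged = h$converged)
}
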
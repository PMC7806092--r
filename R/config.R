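#' Algorithm constants
#'
#' All tunable constants of the tracking pipeline with their defaults:
#' heading updates every 5 s over a 20 s window split into five 4 s
#' sub-windows, a 0.10 m motion sphere with at least three moving
#' sub-windows, a 5 degree coarse grid with 1 degree refinement within
#' +/-5 degrees, convergence after five consecutive estimates within
#' 5 degrees, 5th-order Butterworth low-passes at 0.5 Hz (disagreement)
#' and 2.5 Hz (gyroscope derivative), and the detector's 0.10 m / 20 %
#' rule.
#'
#' @param ... Named overrides of any listed constant.
#' @return Named list of constants.
#' @export
run_config <- function(...) {
  cfg <- list(
    update_period_s = 5,
    window_s = 20,
    n_subwindows = 5,
    min_active_subwindows = 3,
    motion_sphere_m = 0.10,
    coarse_grid_step_deg = 5,
    refine_halfwidth_deg = 5,
    refine_step_deg = 1,
    convergence_len = 5,
    convergence_tol_deg = 5,
    lp_cutoff_accel = 0.5,
    lp_cutoff_gyro = 2.5,
    butterworth_order = 5,
    gravity = 9.81,
    orientation_gain = 0.2,
    detector_threshold_m = 0.10,
    detector_fraction = 0.20
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  cfg
}

#' Segment geometry
#'
#' @param p_imu_to_joint Vector from the IMU to the elbow joint in the
#'   upper-arm frame (m); the frame's x-axis points toward the joint.
#' @param l_A Upper-arm length (m).
#' @param l_p Distance from the proximal forearm cuff to the elbow (m).
#' @return Named list.
#' @export
geometry_config <- function(p_imu_to_joint = c(0.15, 0, 0), l_A = 0.30,
                            l_p = 0.05) {
  stopifnot(sqrt(sum(p_imu_to_joint^2)) > 0, l_A > 0, l_p >= 0)
  list(p_imu_to_joint = p_imu_to_joint, l_A = l_A, l_p = l_p)
}
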
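#' End-to-end tracking, evaluation and sensitivity analysis
#'
#' @name pipeline
NULL

#' Track a trial: orientation, heading, pose
#'
#' Runs the full hybrid pipeline on a pair of measurement streams: the
#' magnetometer-free orientation filter on the IMU stream, the periodic
#' gated heading-offset estimation against the robot stream, and pose
#' reconstruction (hybrid and conventional fixed-shoulder baseline) at the
#' IMU rate.
#'
#' @param imu IMU data frame (`t, gx, gy, gz, ax, ay, az`).
#' @param robot Robot data frame (`t, pex, pey, pez` plus cuff or
#'   forearm-axis columns).
#' @param geometry A [geometry_config()].
#' @param p_S_nom Nominal shoulder position (m, robot frame).
#' @param control A [run_config()].
#' @return List of class `tracking_result`: `pose` (see
#'   [reconstruct_pose()]), `heading` (update log), `orientation`
#'   (quaternion matrix), `geometry`, `p_S_nom`, `control`.
#' @export
track_trial <- function(imu, robot, geometry = geometry_config(),
                        p_S_nom = c(0, 0, 0.9), control = run_config()) {
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  if (!all(need %in% names(imu)))
    stop("IMU stream lacks columns: ", paste(setdiff(need, names(imu)), collapse = ", "))
  if (!all(c("t", "pex", "pey", "pez") %in% names(robot)))
    stop("robot stream lacks the elbow position columns pex, pey, pez")
  if (any(diff(imu$t) <= 0) || any(diff(robot$t) <= 0))
    stop("timestamps must be strictly increasing")
  Q <- estimate_orientation(imu, gain = control$orientation_gain,
                            g = control$gravity)
  hd <- estimate_heading(imu, robot, Q, geometry, control)
  pose <- reconstruct_pose(imu, Q, robot, hd$log, geometry, p_S_nom)
  structure(list(pose = pose, heading = hd$log, orientation = Q,
                 geometry = geometry, p_S_nom = p_S_nom, control = control),
            class = "tracking_result")
}

#' Tracking error metrics against ground truth
#'
#' Computes, for the hybrid and the conventional method, the Euclidean
#' shoulder-position error and the absolute elbow-angle error against the
#' ground truth, reported as time-based medians with 5th/95th percentiles,
#' and when cycle boundaries are supplied also cycle-based (per-cycle mean,
#' then median/percentiles over cycles). Only valid (heading-estimated)
#' samples enter the hybrid metrics.
#'
#' @param pose Pose data frame from [reconstruct_pose()].
#' @param truth Ground-truth data frame on the same time base (columns
#'   `t`, `psx/y/z`, `elbow_deg`).
#' @param cycles Optional cycle-boundary data frame (`t_start`, `t_end`).
#' @param converged_only Restrict to samples after heading convergence.
#' @return List with `time_based` and (if cycles given) `cycle_based`
#'   data frames of medians and percentiles, plus `n_samples`.
#' @export
evaluate_tracking <- function(pose, truth, cycles = NULL,
                              converged_only = TRUE) {
  if (nrow(pose) != nrow(truth) || max(abs(pose$t - truth$t)) > 1e-9)
    stop("pose and truth must share one time base")
  sel <- if (converged_only) pose$converged else pose$valid
  sh_err_hyb <- sqrt((pose$psx - truth$psx)^2 + (pose$psy - truth$psy)^2 +
                       (pose$psz - truth$psz)^2)
  sh_err_conv <- sqrt((pose$ps_conv_x - truth$psx)^2 +
                        (pose$ps_conv_y - truth$psy)^2 +
                        (pose$ps_conv_z - truth$psz)^2)
  el_err_hyb <- abs(pose$elbow_deg - truth$elbow_deg)
  el_err_conv <- abs(pose$elbow_conv_deg - truth$elbow_deg)

  pct <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x),
      p5 = unname(stats::quantile(x, 0.05)),
      p95 = unname(stats::quantile(x, 0.95)))
  }
  tb <- rbind(
    data.frame(method = "hybrid", metric = "shoulder_m",
               t(pct(sh_err_hyb[sel]))),
    data.frame(method = "conventional", metric = "shoulder_m",
               t(pct(sh_err_conv[sel]))),
    data.frame(method = "hybrid", metric = "elbow_deg",
               t(pct(el_err_hyb[sel]))),
    data.frame(method = "conventional", metric = "elbow_deg",
               t(pct(el_err_conv[sel]))))
  out <- list(time_based = tb, n_samples = sum(sel))

  if (!is.null(cycles)) {
    per_cycle <- function(err) {
      vapply(seq_len(nrow(cycles)), function(i) {
        s <- sel & pose$t >= cycles$t_start[i] & pose$t < cycles$t_end[i]
        full <- pose$t >= cycles$t_start[i] & pose$t < cycles$t_end[i]
        # a cycle counts only if wholly usable
        if (!any(full) || !all(sel[full])) return(NA_real_)
        mean(err[s])
      }, numeric(1))
    }
    cyc <- list(shoulder_hyb = per_cycle(sh_err_hyb),
                shoulder_conv = per_cycle(sh_err_conv),
                elbow_hyb = per_cycle(el_err_hyb),
                elbow_conv = per_cycle(el_err_conv))
    cb <- rbind(
      data.frame(method = "hybrid", metric = "shoulder_m",
                 t(pct(cyc$shoulder_hyb))),
      data.frame(method = "conventional", metric = "shoulder_m",
                 t(pct(cyc$shoulder_conv))),
      data.frame(method = "hybrid", metric = "elbow_deg",
                 t(pct(cyc$elbow_hyb))),
      data.frame(method = "conventional", metric = "elbow_deg",
                 t(pct(cyc$elbow_conv))))
    out$cycle_based <- cb
    out$per_cycle <- cyc
    out$n_cycles_used <- sum(!is.na(cyc$shoulder_hyb))
  }
  out
}

#' True heading offset of an orientation-filter run
#'
#' The quantity the heading estimator targets: the wrapped difference
#' between the true segment heading in the robot frame and the estimated
#' heading in the filter's inertial frame, per sample. It includes the
#' filter's drift, so it is the appropriate reference for `delta_hat`.
#'
#' @param Q Estimated quaternions (n x 4) from [estimate_orientation()].
#' @param truth Ground-truth data frame with true `q_RA` columns.
#' @return Numeric vector of offsets in degrees, `[0, 360)`.
#' @export
true_heading_offset <- function(Q, truth) {
  xr <- quat_rotate_rows(cbind(truth$qw, truth$qx, truth$qy, truth$qz),
                         matrix(rep(c(1, 0, 0), each = nrow(truth)), ncol = 3))
  xi <- quat_rotate_rows(Q, matrix(rep(c(1, 0, 0), each = nrow(Q)), ncol = 3))
  wrap_360(rad2deg(atan2(xr[, 2], xr[, 1]) - atan2(xi[, 2], xi[, 1])))
}

#' Parameter sensitivity sweep
#'
#' Re-runs the tracker on one simulated trial with perturbed assumed
#' parameters (IMU-to-joint distance +/-7.5 cm, upper-arm length
#' +/-2.5 cm, gyroscope-derivative cutoff +/-1 Hz) while the data itself is
#' generated with the true values, and reports how the error medians move
#' relative to the unperturbed baseline.
#'
#' @param cfg A [trial_config()] describing the simulated trial.
#' @param d_imu_m,d_lA_m,d_cutoff_hz Perturbation magnitudes.
#' @return Data frame: one row per perturbation (and the baseline) with
#'   shoulder/elbow error medians and their deltas vs. baseline.
#' @export
sensitivity_sweep <- function(cfg, d_imu_m = 0.075, d_lA_m = 0.025,
                              d_cutoff_hz = 1) {
  trial <- simulate_trial(cfg)
  base_geom <- geometry_config(p_imu_to_joint = cfg$p_imu_to_joint,
                               l_A = cfg$l_A, l_p = cfg$l_p)
  runs <- list(
    baseline = list(geom = base_geom, ctrl = run_config()),
    imu_offset_plus = list(
      geom = geometry_config(cfg$p_imu_to_joint + c(d_imu_m, 0, 0),
                             cfg$l_A, cfg$l_p), ctrl = run_config()),
    imu_offset_minus = list(
      geom = geometry_config(cfg$p_imu_to_joint - c(d_imu_m, 0, 0),
                             cfg$l_A, cfg$l_p), ctrl = run_config()),
    l_A_plus = list(
      geom = geometry_config(cfg$p_imu_to_joint, cfg$l_A + d_lA_m, cfg$l_p),
      ctrl = run_config()),
    l_A_minus = list(
      geom = geometry_config(cfg$p_imu_to_joint, cfg$l_A - d_lA_m, cfg$l_p),
      ctrl = run_config()),
    cutoff_plus = list(
      geom = base_geom,
      ctrl = run_config(lp_cutoff_gyro = 2.5 + d_cutoff_hz)),
    cutoff_minus = list(
      geom = base_geom,
      ctrl = run_config(lp_cutoff_gyro = 2.5 - d_cutoff_hz)))
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    tr <- track_trial(trial$imu, trial$robot, r$geom, trial$p_S_nom, r$ctrl)
    ev <- evaluate_tracking(tr$pose, trial$truth, trial$cycles)
    tb <- ev$time_based
    data.frame(run = nm,
               shoulder_median_m = tb$median[tb$method == "hybrid" &
                                               tb$metric == "shoulder_m"],
               elbow_median_deg = tb$median[tb$method == "hybrid" &
                                              tb$metric == "elbow_deg"])
  })
  out <- do.call(rbind, rows)
  out$d_shoulder_m <- out$shoulder_median_m - out$shoulder_median_m[1]
  out$d_elbow_deg <- out$elbow_median_deg - out$elbow_median_deg[1]
  out
}
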
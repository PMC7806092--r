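#' Detection of compensatory shoulder motion
#'
#' Patients compensating reduced shoulder/elbow mobility displace the
#' shoulder by around 14 cm per reach, versus about 4 cm in proper
#' movements. A completed motion cycle is classified as compensatory when
#' the estimated shoulder leaves a radial tolerance of 0.10 m around the
#' nominal shoulder position for more than 20 % of the cycle duration
#' (displacements for up to 20 % are tolerated). A three-state indicator
#' (green / blue / orange) drives real-time biofeedback.
#'
#' @name compensation_detector
NULL

#' Euclidean shoulder displacement from the nominal position
#'
#' @param p_S Shoulder position(s): length-3 vector or n x 3 matrix.
#' @param p_S_nom Nominal shoulder position.
#' @param planar Restrict the distance to the horizontal (x, y) plane.
#' @return Displacement(s) in meters.
#' @export
shoulder_displacement <- function(p_S, p_S_nom, planar = FALSE) {
  if (is.null(dim(p_S))) p_S <- matrix(p_S, ncol = 3)
  d <- p_S - matrix(rep(p_S_nom, each = nrow(p_S)), ncol = 3)
  if (planar) d[, 3] <- 0
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

#' Classify one completed motion cycle
#'
#' The out-of-range fraction is the time-weighted share of the cycle during
#' which the shoulder displacement exceeds `threshold_m`; the cycle is
#' compensatory when this fraction strictly exceeds `fraction_limit`.
#' Cycles containing invalid poses (heading not yet estimated) are reported
#' unclassifiable rather than guessed.
#'
#' @param t Sample times within the cycle (s).
#' @param p_S n x 3 matrix of estimated shoulder positions.
#' @param p_S_nom Nominal shoulder position (m).
#' @param threshold_m Radial displacement tolerance (m).
#' @param fraction_limit Tolerated out-of-range fraction of the cycle.
#' @param planar Use horizontal-plane displacement only.
#' @param valid Optional logical vector; any `FALSE` makes the cycle
#'   unclassifiable.
#' @return List with `label` (`"proper"`, `"compensatory"` or
#'   `"unclassifiable"`), `out_of_range_fraction`, `threshold_m`,
#'   `fraction_limit`.
#' @export
classify_cycle <- function(t, p_S, p_S_nom, threshold_m = 0.10,
                           fraction_limit = 0.20, planar = FALSE,
                           valid = NULL) {
  if (length(t) == 0) stop("classify_cycle: empty cycle")
  if (!is.null(valid) && !all(valid)) {
    return(list(label = "unclassifiable", out_of_range_fraction = NA_real_,
                threshold_m = threshold_m, fraction_limit = fraction_limit))
  }
  disp <- shoulder_displacement(p_S, p_S_nom, planar = planar)
  over <- disp > threshold_m
  n <- length(t)
  if (n == 1) {
    frac <- as.numeric(over)
  } else {
    # time weight of each sample: half the gap to each neighbour
    w <- (c(diff(t), 0) + c(0, diff(t))) / 2
    frac <- sum(w[over]) / sum(w)
  }
  label <- if (frac > fraction_limit) "compensatory" else "proper"
  list(label = label, out_of_range_fraction = frac,
       threshold_m = threshold_m, fraction_limit = fraction_limit)
}

#' Classify all cycles of a tracked trial
#'
#' @param pose Pose data frame from [reconstruct_pose()].
#' @param cycles Data frame with columns `t_start`, `t_end` (and optionally
#'   `label` with ground truth).
#' @param p_S_nom Nominal shoulder position (m).
#' @param threshold_m,fraction_limit,planar See [classify_cycle()].
#' @param require_converged Treat poses before heading convergence as
#'   invalid for classification.
#' @return Data frame with one row per cycle: `cycle`, `t_start`, `t_end`,
#'   `fraction_out`, `label`, and `truth` if provided.
#' @export
classify_cycles <- function(pose, cycles, p_S_nom, threshold_m = 0.10,
                            fraction_limit = 0.20, planar = FALSE,
                            require_converged = TRUE) {
  out <- lapply(seq_len(nrow(cycles)), function(i) {
    sel <- pose$t >= cycles$t_start[i] & pose$t < cycles$t_end[i]
    if (!any(sel)) {
      return(data.frame(cycle = i, t_start = cycles$t_start[i],
                        t_end = cycles$t_end[i], fraction_out = NA_real_,
                        label = "unclassifiable"))
    }
    ok <- if (require_converged) pose$converged[sel] else pose$valid[sel]
    res <- classify_cycle(pose$t[sel],
                          cbind(pose$psx, pose$psy, pose$psz)[sel, , drop = FALSE],
                          p_S_nom, threshold_m, fraction_limit, planar,
                          valid = ok)
    data.frame(cycle = i, t_start = cycles$t_start[i],
               t_end = cycles$t_end[i],
               fraction_out = res$out_of_range_fraction, label = res$label)
  })
  out <- do.call(rbind, out)
  if (!is.null(cycles$label)) out$truth <- cycles$label
  out
}

#' Three-state biofeedback indicator
#'
#' `green` while the shoulder displacement is within the tolerance;
#' `blue` once it exceeds the tolerance; `orange` when it has been outside
#' for longer than the maximum tolerated duration.
#'
#' @param displacement_m Current shoulder displacement (m).
#' @param over_limit_duration_s How long the displacement has continuously
#'   exceeded the tolerance (s).
#' @param max_tolerated_s Maximum tolerated out-of-range duration (s);
#'   typically a percentage of the current cycle duration.
#' @param threshold_m Displacement tolerance (m).
#' @return One of `"green"`, `"blue"`, `"orange"`.
#' @export
biofeedback_state <- function(displacement_m, over_limit_duration_s,
                              max_tolerated_s, threshold_m = 0.10) {
  stopifnot(displacement_m >= 0, over_limit_duration_s >= 0,
            max_tolerated_s >= 0)
  if (displacement_m <= threshold_m) return("green")
  if (over_limit_duration_s <= max_tolerated_s) return("blue")
  "orange"
}

#' Confusion table of cycle classifications against ground truth
#'
#' @param detections Data frame from [classify_cycles()] with a `truth`
#'   column.
#' @return List with `table` (truth x predicted counts, classifiable cycles
#'   only), `n_unclassifiable`, and `accuracy` (fraction correct).
#' @export
detection_confusion <- function(detections) {
  stopifnot(!is.null(detections$truth))
  cl <- detections[detections$label != "unclassifiable", ]
  tab <- table(truth = cl$truth, predicted = cl$label)
  list(table = tab,
       n_unclassifiable = sum(detections$label == "unclassifiable"),
       accuracy = if (nrow(cl)) mean(cl$truth == cl$label) else NA_real_)
}
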
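#' Causal low-pass filtering and numerical differentiation
#'
#' The heading estimator compares accelerations derived from two different
#' sensors, so both signals pass through identical causal 5th-order
#' Butterworth low-pass filters (the shared phase delay cancels in their
#' difference). Filtering is forward-only; the startup transient is removed
#' by padding with the first sample before filtering.
#'
#' @name filtering
NULL

# Causal Butterworth low-pass per column. x: vector or matrix (columns are
# channels), fs in Hz. pad_s seconds of constant padding absorb the
# filter's startup transient.
butter_lowpass <- function(x, cutoff_hz, fs, order = 5, pad_s = 4) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("stream too short for filtering")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  npad <- max(1L, round(pad_s * fs))
  out <- x
  for (j in seq_len(ncol(x))) {
    xp <- c(rep(x[1, j], npad), x[, j])
    yp <- as.numeric(signal::filter(bf, xp))
    out[, j] <- yp[(npad + 1):length(yp)]
  }
  out
}

# Passband group delay of the causal Butterworth low-pass, in samples,
# measured from the phase of a filtered probe sinusoid well inside the
# passband. Used to content-align the differentiated gyroscope signal with
# the unfiltered channels.
butter_group_delay_samples <- function(cutoff_hz, fs, order = 5) {
  f_ref <- cutoff_hz / 10
  ncyc <- 8
  t <- seq(0, ncyc / f_ref, by = 1 / fs)
  w <- 2 * pi * f_ref
  x <- sin(w * t)
  y <- butter_lowpass(matrix(x, ncol = 1), cutoff_hz, fs, order,
                      pad_s = 3 / cutoff_hz)[, 1]
  keep <- t > (2 / f_ref)  # integer cycles, past any residual transient
  b1 <- 2 * mean(y[keep] * sin(w * t[keep]))
  b2 <- 2 * mean(y[keep] * cos(w * t[keep]))
  round(-atan2(b2, b1) / w * fs)
}

#' Low-pass filtered derivative of the angular rate
#'
#' Applies a causal 5th-order Butterworth low-pass (default cutoff 2.5 Hz)
#' to each gyroscope axis, then differentiates by finite differences.
#'
#' @param gyro n x 3 matrix of angular rates (rad/s), uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param order Butterworth order.
#' @return n x 3 matrix of angular accelerations (rad/s^2).
#' @export
gyro_derivative <- function(gyro, fs, cutoff_hz = 2.5, order = 5) {
  g <- butter_lowpass(as.matrix(gyro), cutoff_hz, fs, order)
  dt <- 1 / fs
  n <- nrow(g)
  d <- matrix(0, n, ncol(g))
  if (n >= 3) {
    d[2:(n - 1), ] <- (g[3:n, , drop = FALSE] - g[1:(n - 2), , drop = FALSE]) / (2 * dt)
    d[1, ] <- (g[2, ] - g[1, ]) / dt
    d[n, ] <- (g[n, ] - g[n - 1, ]) / dt
  }
  d
}

#' Second time derivative of a position stream
#'
#' Second-order central differences per axis; exact for quadratic
#' trajectories at interior samples. End samples replicate their neighbours.
#'
#' @param p n x 3 matrix of positions (m), uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @return n x 3 matrix of accelerations (m/s^2).
#' @export
robot_joint_accel <- function(p, fs) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 samples for a second derivative")
  dt2 <- (1 / fs)^2
  a <- matrix(0, n, ncol(p))
  a[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - 2 * p[2:(n - 1), , drop = FALSE] +
                       p[1:(n - 2), , drop = FALSE]) / dt2
  a[1, ] <- a[2, ]
  a[n, ] <- a[n - 1, ]
  a
}

#' Low-pass filter used on both sides of the acceleration disagreement
#'
#' Causal 5th-order Butterworth, default cutoff 0.5 Hz, applied identically
#' to the IMU-derived and robot-derived joint accelerations.
#'
#' @param x n x k matrix (or vector), uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff in Hz.
#' @param order Butterworth order.
#' @export
smooth_for_disagreement <- function(x, fs, cutoff_hz = 0.5, order = 5) {
  butter_lowpass(x, cutoff_hz, fs, order)
}
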
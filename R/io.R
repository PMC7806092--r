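#' Stream file I/O
#'
#' Measurement streams, ground truth, poses and cycle tables are stored as
#' plain CSV with a header row; lines starting with `#` carry units and
#' provenance comments and are ignored on read. Timestamps are seconds,
#' positions meters, angular rates rad/s, specific forces m/s^2.
#'
#' @name io
NULL

#' Write a stream data frame to CSV
#'
#' @param x Data frame with a `t` column.
#' @param path Output file path.
#' @param comments Character vector of comment lines (written prefixed
#'   with `# `).
#' @export
write_stream_csv <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.csv(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stream CSV written by [write_stream_csv()]
#'
#' @param path File path.
#' @param allow_na Permit missing values in non-time columns (pose files
#'   legitimately contain NA before the heading estimate exists;
#'   measurement streams must be complete).
#' @return Data frame; errors if a `t` column is missing or non-monotone.
#' @export
read_stream_csv <- function(path, allow_na = FALSE) {
  x <- utils::read.csv(path, comment.char = "#")
  if (!"t" %in% names(x)) stop("stream file lacks a 't' column: ", path)
  if (!allow_na && anyNA(x)) stop("stream file contains missing cells: ", path)
  if (anyNA(x$t)) stop("stream file has missing timestamps: ", path)
  if (any(diff(x$t) <= 0)) stop("non-monotone timestamps in ", path)
  x
}

#' Write all files of a synthetic trial
#'
#' Writes `imu.csv`, `robot.csv`, `truth.csv` and `cycles.csv` into a
#' directory.
#'
#' @param trial A `synthetic_trial` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- trial$config
  hdr <- c(sprintf("seed=%d shoulder_amp_m=%g cycle_period_s=%g n_cycles=%d",
                   cfg$seed, cfg$shoulder_amp_m, cfg$cycle_period_s,
                   as.integer(cfg$n_cycles)),
           "units: t s, positions m, gyro rad/s, acc m/s^2")
  write_stream_csv(trial$imu, file.path(dir, "imu.csv"), hdr)
  write_stream_csv(trial$robot, file.path(dir, "robot.csv"), hdr)
  write_stream_csv(trial$truth, file.path(dir, "truth.csv"), hdr)
  cyc <- trial$cycles
  utils::write.csv(cyc, file.path(dir, "cycles.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
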
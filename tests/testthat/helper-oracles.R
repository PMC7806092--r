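# Independent oracles used across the test files.

# Rotation matrix from axis and angle via the Rodrigues formula —
# independent of the package's quaternion code.
rodrigues <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rz_mat <- function(deg) rodrigues(c(0, 0, 1), deg * pi / 180)

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# Brute-force heading cost: rotate every window sample by the candidate
# heading with a rotation matrix and sum squared differences. Deliberately
# naive; the reference for heading_cost()/optdelta().
brute_cost <- function(delta_deg, a_I, pdd_R) {
  R <- rz_mat(delta_deg)
  sum(vapply(seq_len(nrow(a_I)), function(k) {
    sum((as.numeric(R %*% a_I[k, ]) - pdd_R[k, ])^2)
  }, numeric(1)))
}

brute_optdelta <- function(grid_deg, a_I, pdd_R) {
  costs <- vapply(grid_deg, brute_cost, numeric(1), a_I = a_I, pdd_R = pdd_R)
  grid_deg[which.min(costs)]
}

# A random informative window: accelerations with non-collinear horizontal
# components, and the robot-side signal constructed as Rz(delta0) times the
# inertial signal (the exact-recovery construction).
make_window <- function(m, delta0_deg, noise_sd = 0) {
  a <- matrix(stats::rnorm(3 * m), m, 3)
  R <- rz_mat(delta0_deg)
  p <- t(R %*% t(a)) + matrix(stats::rnorm(3 * m, sd = noise_sd), m, 3)
  list(a = a, p = p)
}

# Minimal static measurement streams (no motion at all).
static_streams <- function(duration_s = 30, imu_rate = 100, robot_rate = 25) {
  t_imu <- seq(0, duration_s, by = 1 / imu_rate)
  t_rob <- seq(0, duration_s, by = 1 / robot_rate)
  list(imu = data.frame(t = t_imu, gx = 0, gy = 0, gz = 0,
                        ax = 0, ay = 0, az = 9.81),
       robot = data.frame(t = t_rob, pex = 0.2, pey = 0.3, pez = 0.9,
                          pwx = 0.2, pwy = 0.55, pwz = 0.9,
                          ppx = 0.2, ppy = 0.35, ppz = 0.9))
}
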
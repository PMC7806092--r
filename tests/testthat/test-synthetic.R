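test_that("shoulder displacement amplitude is honored by construction", {
  cfg0 <- trial_config(n_cycles = 2, shoulder_amp_m = 0, seed = 61)
  tr0 <- generate_arm_motion(cfg0)
  disp0 <- shoulder_displacement(cbind(tr0$psx, tr0$psy, tr0$psz),
                                 cfg0$p_S_nom)
  expect_equal(max(disp0), 0)
  cfg1 <- trial_config(n_cycles = 2, shoulder_amp_m = 0.14,
                       cycle_period_s = 5.4, seed = 61)
  tr1 <- generate_arm_motion(cfg1)
  disp1 <- shoulder_displacement(cbind(tr1$psx, tr1$psy, tr1$psz),
                                 cfg1$p_S_nom)
  expect_equal(max(disp1), 0.14, tolerance = 1e-6)
})

test_that("ground truth satisfies the rigid-segment and cuff-geometry constraints", {
  cfg <- trial_config(n_cycles = 3, shoulder_amp_m = 0.14,
                      cycle_period_s = 5.4, seed = 62)
  tr <- generate_arm_motion(cfg)
  seg <- sqrt((tr$psx - tr$pex)^2 + (tr$psy - tr$pey)^2 +
                (tr$psz - tr$pez)^2)
  expect_lt(max(abs(seg - cfg$l_A)), 1e-9)
  fore <- sqrt((tr$pwx - tr$pex)^2 + (tr$pwy - tr$pey)^2 +
                 (tr$pwz - tr$pez)^2)
  expect_lt(max(abs(fore - cfg$l_F)), 1e-9)
  # cuff extrapolation reproduces the elbow exactly
  for (k in c(1, 250, 700)) {
    pe <- elbow_from_cuffs(c(tr$pwx[k], tr$pwy[k], tr$pwz[k]),
                           c(tr$ppx[k], tr$ppy[k], tr$ppz[k]), cfg$l_p)
    expect_equal(pe, c(tr$pex[k], tr$pey[k], tr$pez[k]), tolerance = 1e-9)
  }
})

test_that("an unreachable hand path is reported", {
  cfg <- trial_config(n_cycles = 1, rect_center_xy = c(0, 0.6), seed = 63)
  expect_error(generate_arm_motion(cfg), "unreachable")
})

test_that("a static pose yields zero rates and gravity-only specific force", {
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  truth <- data.frame(t = t, qw = 1, qx = 0, qy = 0, qz = 0,
                      psx = 0, psy = 0, psz = 0.9,
                      pex = 0.3, pey = 0, pez = 0.9,
                      pwx = 0.3, pwy = 0.25, pwz = 0.9,
                      ppx = 0.3, ppy = 0.05, ppz = 0.9,
                      xcx = 0, xcy = -1, xcz = 0, elbow_deg = 90)
  cfg <- trial_config(n_cycles = 1, gyro_bias_deg_s = 0,
                      gyro_noise_sd_deg_s = 0, acc_noise_sd = 0, seed = 64)
  imu <- simulate_imu(truth, cfg)
  expect_equal(max(abs(c(imu$gx, imu$gy, imu$gz))), 0)
  expect_equal(sqrt(imu$ax^2 + imu$ay^2 + imu$az^2), rep(9.81, n),
               tolerance = 1e-9)
})

test_that("zero-noise robot samples lie on the truth at exactly the robot rate", {
  cfg <- trial_config(n_cycles = 4, robot_pos_noise_sd = 0, seed = 65)
  truth <- generate_arm_motion(cfg)
  rob <- simulate_robot(truth, cfg)
  dur <- cfg$n_cycles * cfg$cycle_period_s
  expect_lte(abs(nrow(rob) - dur * cfg$robot_rate_hz), 1 + 1e-9)
  expect_equal(stats::median(diff(rob$t)), 1 / cfg$robot_rate_hz,
               tolerance = 1e-12)
  k <- match(rob$t, truth$t)
  expect_equal(rob$pex, truth$pex[k])
  expect_equal(rob$ppy, truth$ppy[k])
})

test_that("the simulated accelerometer closes the joint-acceleration loop", {
  cfg <- trial_config(n_cycles = 4, gyro_bias_deg_s = 0,
                      gyro_noise_sd_deg_s = 0, acc_noise_sd = 0,
                      robot_pos_noise_sd = 0, seed = 66)
  trial <- simulate_trial(cfg)
  imu <- trial$imu; truth <- trial$truth
  fs <- cfg$imu_rate_hz
  G <- cbind(imu$gx, imu$gy, imu$gz)
  # noise-free data: differentiate the raw rate directly (no pre-filter)
  n <- nrow(G); dt <- 1 / fs
  GD <- matrix(0, n, 3)
  GD[2:(n - 1), ] <- (G[3:n, ] - G[1:(n - 2), ]) / (2 * dt)
  GD[1, ] <- GD[2, ]; GD[n, ] <- GD[n - 1, ]
  Qt <- cbind(truth$qw, truth$qx, truth$qy, truth$qz)
  # elbow acceleration from the truth trajectory
  PE <- cbind(truth$pex, truth$pey, truth$pez)
  AE <- robot_joint_accel(PE, fs)
  mid <- 200:(nrow(imu) - 200)
  errs <- vapply(mid[seq(1, length(mid), by = 37)], function(k) {
    sf <- joint_specific_force(c(imu$ax[k], imu$ay[k], imu$az[k]),
                               G[k, ], GD[k, ], cfg$p_imu_to_joint)
    aI <- joint_acceleration_inertial(sf, Qt[k, ])
    sqrt(sum((aI - AE[k, ])^2))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)  # differencing tolerance only
})

test_that("identical configuration and seed give bit-identical streams", {
  cfg <- trial_config(n_cycles = 2, seed = 67)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$imu, t2$imu)
  expect_identical(t1$robot, t2$robot)
  expect_identical(t1$truth, t2$truth)
  t3 <- simulate_trial(trial_config(n_cycles = 2, seed = 68))
  expect_false(identical(t1$imu, t3$imu))
})
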
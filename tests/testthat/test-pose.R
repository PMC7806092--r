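test_that("elbow_from_cuffs extrapolates the cuff line into the joint", {
  expect_equal(elbow_from_cuffs(c(0, -0.25, 0), c(0, 0, 0), 0.1),
               c(0, 0.1, 0))
  expect_equal(elbow_from_cuffs(c(0, -0.25, 0), c(0, 0, 0), 0), c(0, 0, 0))
  expect_equal(elbow_from_cuffs(c(1, 0, 0), c(1, 1, 0), 0.05),
               c(1, 1.05, 0))
  expect_error(elbow_from_cuffs(c(1, 1, 0), c(1, 1, 0), 0.05), "coincident")
})

test_that("segment_orientation_R applies the heading offset", {
  q <- quat_normalize(quat(0.9, 0.1, -0.2, 0.3))
  expect_equal(segment_orientation_R(q, 0), q)
  expect_equal(segment_orientation_R(quat_identity(), 90), heading_quat(90))
  q_RA <- segment_orientation_R(q, 40)
  expect_equal(quat_rotate(q_RA, c(1, 0, 0)),
               as.numeric(rz_mat(40) %*% quat_rotate(q, c(1, 0, 0))),
               tolerance = 1e-12)
  expect_error(segment_orientation_R(q, NA_real_), "not yet estimated")
})

test_that("elbow_angle is the planar angle between segment axes", {
  expect_equal(elbow_angle(c(1, 0, 0), quat_identity()), 0)
  expect_equal(elbow_angle(c(0, 1, 0), quat_identity()), 90)
  expect_equal(elbow_angle(c(1, 0, 0), heading_quat(135)), 135,
               tolerance = 1e-12)
})

test_that("elbow_angle is invariant under a common rotation of both segments", {
  set.seed(41)
  for (i in 1:20) {
    q_RA <- random_unit_quat()
    x_C <- normalize_vec(stats::rnorm(3))
    base <- elbow_angle(x_C, q_RA)
    g <- random_unit_quat()
    expect_equal(elbow_angle(quat_rotate(g, x_C), quat_multiply(g, q_RA)),
                 base, tolerance = 1e-9)
  }
})

test_that("shoulder_position walks back along the upper-arm axis", {
  expect_equal(shoulder_position(c(0, 0, 0), quat_identity(), 0.3),
               c(-0.3, 0, 0))
  expect_equal(shoulder_position(c(0, 0, 0), heading_quat(90), 0.3),
               c(0, -0.3, 0), tolerance = 1e-12)
  expect_error(shoulder_position(c(0, 0, 0), quat_identity(), 0), "positive")
  # rigid-segment consistency for arbitrary poses
  set.seed(42)
  for (i in 1:50) {
    q <- random_unit_quat(); p_E <- stats::rnorm(3); l_A <- stats::runif(1, 0.2, 0.4)
    p_S <- shoulder_position(p_E, q, l_A)
    expect_equal(sqrt(sum((p_S - p_E)^2)), l_A, tolerance = 1e-12)
  }
})

test_that("shoulder_position round-trips the simulator's ground truth", {
  cfg <- trial_config(n_cycles = 3, seed = 43)
  truth <- generate_arm_motion(cfg)
  for (k in c(1, 100, 500)) {
    q <- c(truth$qw[k], truth$qx[k], truth$qy[k], truth$qz[k])
    p_S <- shoulder_position(c(truth$pex[k], truth$pey[k], truth$pez[k]),
                             q, cfg$l_A)
    expect_equal(p_S, c(truth$psx[k], truth$psy[k], truth$psz[k]),
                 tolerance = 1e-9)
  }
})

test_that("a 1-degree orientation error moves a half-meter endpoint by less than 1 cm", {
  l_A <- 0.5
  bound <- 2 * l_A * sin(0.5 * pi / 180)
  expect_lt(bound, 0.01)
  set.seed(44)
  worst <- 0
  for (i in 1:200) {
    q <- random_unit_quat()
    ax <- normalize_vec(stats::rnorm(3))
    q_err <- quat_multiply(quat_from_axis_angle(ax, 1 * pi / 180), q)
    shift <- sqrt(sum((shoulder_position(c(0, 0, 0), q_err, l_A) -
                         shoulder_position(c(0, 0, 0), q, l_A))^2))
    worst <- max(worst, shift)
  }
  expect_lte(worst, bound + 1e-12)
})

test_that("the conventional baseline pins the shoulder and reads the angle off the nominal axis", {
  res <- conventional_pose(c(0, 0.3, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(res$p_S, c(0, 0, 0))
  expect_equal(res$elbow_deg, 90)
  # with the elbow rigidly following a displaced shoulder, the baseline's
  # shoulder error equals the displacement exactly
  d <- c(0.1, 0.05, 0)
  p_S_true <- c(0, 0, 0) + d
  expect_equal(sqrt(sum((conventional_pose(p_S_true + c(0.3, 0, 0),
                                           c(0, 0, 0),
                                           c(0, 1, 0))$p_S - p_S_true)^2)),
               sqrt(sum(d^2)))
})
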
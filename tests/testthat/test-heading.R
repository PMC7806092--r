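test_that("joint_specific_force adds the radial and tangential terms", {
  acc <- c(0.4, -0.2, 9.6)
  expect_equal(joint_specific_force(acc, c(0, 0, 0), c(0, 0, 0),
                                    c(0.15, 0, 0)), acc)
  # centripetal term: (w x)^2 p = w (w.p) - |w|^2 p = -4 * p
  expect_equal(joint_specific_force(c(0, 0, 9.81), c(0, 0, 2), c(0, 0, 0),
                                    c(0.15, 0, 0)),
               c(-0.6, 0, 9.81))
  # tangential term: wdot x p
  expect_equal(joint_specific_force(c(0, 0, 0), c(0, 0, 0), c(0, 0, 3),
                                    c(0.2, 0, 0)),
               c(0, 0.6, 0))
  # cross-check against a finite-difference oracle: point rotating about z
  w <- 1.3; r <- 0.15; dt <- 1e-5
  pos <- function(t) r * c(cos(w * t), sin(w * t), 0)
  a_num <- (pos(dt) - 2 * pos(0) + pos(-dt)) / dt^2
  # at t=0 the body and world frames align; the accelerometer at the
  # center reads gravity only, so the joint specific force is gravity
  # plus the rotational acceleration of the joint point
  sf <- joint_specific_force(c(0, 0, 9.81), c(0, 0, w), c(0, 0, 0),
                             c(r, 0, 0))
  expect_equal(sf - c(0, 0, 9.81), a_num, tolerance = 1e-6)
})

test_that("joint_acceleration_inertial rotates and removes gravity", {
  expect_equal(joint_acceleration_inertial(c(0, 0, 9.81), quat_identity()),
               c(0, 0, 0))
  expect_equal(joint_acceleration_inertial(c(1, 0, 9.81), quat_identity()),
               c(1, 0, 0))
  expect_equal(joint_acceleration_inertial(c(1, 0, 9.81), heading_quat(90)),
               c(0, 1, 0), tolerance = 1e-12)
})

test_that("disagreement and heading_cost match hand calculations", {
  a <- c(1, 0, 0)
  expect_equal(disagreement(0, a, a), c(0, 0, 0))
  expect_equal(disagreement(90, c(1, 0, 0), c(0, 1, 0)), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(disagreement(90, c(1, 0, 0), c(1, 0, 0)), c(-1, 1, 0),
               tolerance = 1e-12)
  aw <- matrix(c(1, 0, 0), 1)
  pw <- matrix(c(0, 1, 0), 1)
  expect_equal(heading_cost(0, aw, pw), 2, tolerance = 1e-12)
  expect_equal(heading_cost(90, aw, pw), 0, tolerance = 1e-12)
  # perfectly matched window has zero cost at the true offset
  set.seed(31)
  w <- make_window(30, 40)
  expect_lt(heading_cost(40, w$a, w$p), 1e-20 * heading_cost(0, w$a, w$p) + 1e-12)
  # 360-degree periodicity
  d <- stats::runif(10, -720, 720)
  expect_equal(heading_cost(d, w$a, w$p), heading_cost(d + 360, w$a, w$p),
               tolerance = 1e-9)
})

test_that("heading_cost and optdelta agree with the brute-force oracle", {
  set.seed(32)
  grid <- 0:359
  for (i in 1:100) {
    w <- make_window(12, stats::runif(1, 0, 360), noise_sd = 0.5)
    expect_equal(heading_cost(grid, w$a, w$p),
                 vapply(grid, brute_cost, numeric(1), w$a, w$p),
                 tolerance = 1e-9)
    expect_equal(optdelta(grid, w$a, w$p), brute_optdelta(grid, w$a, w$p))
  }
})

test_that("optdelta recovers the true offset on a noise-free window, coarse then refined", {
  set.seed(33)
  w <- make_window(50, 40)
  expect_equal(optdelta(seq(0, 355, by = 5), w$a, w$p), 40)
  w2 <- make_window(50, 42)
  coarse <- optdelta(seq(0, 355, by = 5), w2$a, w2$p)
  expect_equal(coarse, 40)
  expect_equal(optdelta(seq(coarse - 5, coarse + 5, by = 1), w2$a, w2$p), 42)
})

test_that("optdelta tie-break on a degenerate window is the smallest wrapped angle", {
  zero <- matrix(0, 10, 3)
  expect_equal(optdelta(seq(0, 355, by = 5), zero, zero), 0)
  expect_equal(optdelta(c(90, 270, 180), zero, zero), 90)
  expect_error(optdelta(numeric(0), zero, zero), "empty grid")
})

test_that("a purely vertical joint acceleration leaves the cost flat in delta", {
  a <- cbind(0, 0, stats::rnorm(40))
  p <- a
  costs <- heading_cost(0:359, a, p)
  expect_lt(diff(range(costs)), 1e-12)
})

test_that("motion_gate applies the three-of-five sub-window rule", {
  still <- matrix(rep(c(0.2, 0.3, 0.9), each = 500), ncol = 3)
  expect_false(motion_gate(still))
  sweep <- cbind(seq(0, 1, length.out = 500), 0.3, 0.9)  # 0.2 m per sub-window
  expect_true(motion_gate(sweep))
  # motion of 0.2 m in exactly k sub-windows, frozen otherwise
  make_pe <- function(k_active) {
    x <- numeric(500)
    for (k in seq_len(5)) {
      i <- ((k - 1) * 100 + 1):(k * 100)
      x[i] <- if (k <= k_active) seq(0, 0.2, length.out = 100) else 0
    }
    cbind(x, 0.3, 0.9)
  }
  expect_false(motion_gate(make_pe(2)))
  expect_true(motion_gate(make_pe(3)))
  # boundary: staying exactly within a 0.10 m diameter is not motion
  border <- cbind(rep(c(0, 0.099), 250), 0.3, 0.9)
  expect_false(motion_gate(border))
  expect_error(motion_gate(matrix(0, 3, 3)), "shorter")
})

test_that("update_heading converges after five stable two-step estimates", {
  set.seed(34)
  st <- heading_state()
  expect_true(is.na(st$delta_hat))
  for (i in 1:5) {
    w <- make_window(40, 73)
    st <- update_heading(st, w$a, w$p, gated = TRUE, t = 20 + 5 * i)
    expect_equal(st$delta_tilde, 75)  # coarse grid quantizes to 5 degrees
    expect_equal(st$delta_hat, 73)   # refinement recovers the offset
    if (i < 5) expect_false(st$converged)
  }
  expect_true(st$converged)
  expect_equal(st$history, rep(73, 5))
})

test_that("the convergence rule accepts five estimates changing by at most 5 degrees", {
  st <- heading_state()
  st$history <- c(100, 103, 101, 98, 100)
  w <- make_window(20, 100)
  st2 <- update_heading(st, w$a, w$p, gated = TRUE, t = 50)
  expect_true(st2$converged)
  st$history <- c(100, 109, 101, 98, 100)  # one 8-degree jump in the last five
  st3 <- update_heading(st, w$a, w$p, gated = TRUE, t = 50)
  expect_false(st3$converged)
})

test_that("non-gated windows leave the estimate untouched and do not reset the streak", {
  set.seed(35)
  st <- heading_state()
  for (i in 1:3) {
    w <- make_window(40, 50)
    st <- update_heading(st, w$a, w$p, gated = TRUE, t = 20 + 5 * i)
  }
  h_before <- st$history
  st <- update_heading(st, NULL, NULL, gated = FALSE, t = 40)
  expect_equal(st$history, h_before)
  expect_equal(st$delta_hat, 50)
  for (i in 4:5) {
    w <- make_window(40, 50)
    st <- update_heading(st, w$a, w$p, gated = TRUE, t = 25 + 5 * i)
  }
  expect_true(st$converged)
})

test_that("the converged one-step update tracks a drift of 0.3 deg/s", {
  set.seed(36)
  st <- heading_state()
  delta0 <- 120
  for (i in 1:5) {  # converge at a constant offset
    w <- make_window(40, delta0)
    st <- update_heading(st, w$a, w$p, gated = TRUE, t = 5 * i)
  }
  expect_true(st$converged)
  for (i in 6:25) {  # 0.3 deg/s drift, 1.5 degrees per 5 s update
    d_true <- delta0 + 0.3 * 5 * (i - 5)
    w <- make_window(40, d_true)
    st <- update_heading(st, w$a, w$p, gated = TRUE, t = 5 * i)
    expect_lte(abs(wrap_angle(st$delta_hat - d_true)), 1)
  }
})

test_that("exact recovery across true offsets on a 7-degree grid", {
  set.seed(37)
  for (delta0 in seq(0, 359, by = 7)) {
    st <- heading_state()
    for (i in 1:5) {
      w <- make_window(30, delta0)
      st <- update_heading(st, w$a, w$p, gated = TRUE, t = 5 * i)
    }
    expect_true(st$converged)
    expect_lte(abs(wrap_angle(st$delta_hat - delta0)), 1)
  }
})

test_that("heading equivariance: rotating the robot-frame inputs shifts the estimate", {
  set.seed(38)
  for (alpha in c(30, 127, 300)) {
    w <- make_window(40, 75, noise_sd = 0.2)
    base <- optdelta(0:359, w$a, w$p)
    R <- rz_mat(alpha)
    rotated <- optdelta(0:359, w$a, t(R %*% t(w$p)))
    expect_lte(abs(wrap_angle(rotated - base - alpha)), 1)
  }
})
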
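noise <- noise_config()

test_that("strapdown prediction: gravity cancellation, velocity advance, constant-rate heading", {
  x <- erkf_state(list(foot_l = list(p = c(0, 0, 0), v = c(0, 0, 0),
                                     q = c(1, 0, 0, 0))))
  # stationary level IMU senses +9.81 on z; state must not move
  u <- list(a = matrix(c(0, 0, 9.81), 1), w = matrix(0, 1, 3))
  x1 <- predict_state(x, u, 1 / 128, noise)
  expect_equal(x1$p[1, ], c(0, 0, 0), tolerance = 1e-15)
  expect_equal(x1$v[1, ], c(0, 0, 0), tolerance = 1e-15)
  expect_equal(x1$q[1, ], c(1, 0, 0, 0))

  # constant velocity with gravity-cancelling specific force
  x$v[1, ] <- c(1, 0, 0)
  x2 <- predict_state(x, u, 1 / 128, noise)
  expect_equal(x2$p[1, ], c(1 / 128, 0, 0), tolerance = 1e-15)

  # 1 s of constant omega about z advances heading by |omega| * 1 s
  om <- 0.7
  u <- list(a = matrix(c(0, 0, 9.81), 1), w = matrix(c(0, 0, om), 1))
  xk <- x
  for (k in 1:128) xk <- predict_state(xk, u, 1 / 128, noise)
  expect_equal(quat_to_rotvec(xk$q[1, ]), c(0, 0, om), tolerance = 1e-6)

  expect_error(predict_state(x, list(a = matrix(NaN, 1, 3),
                                     w = matrix(0, 1, 3)), 1 / 128, noise),
               "non-finite")
})

test_that("process Jacobian: zero-input block, finite-difference oracle, 7-IMU structure", {
  x <- erkf_state(list(foot_l = list(p = c(0, 0, 0), v = c(0, 0, 0),
                                     q = c(1, 0, 0, 0))))
  dt <- 1 / 128
  u0 <- list(a = matrix(0, 1, 3), w = matrix(0, 1, 3))
  Fx <- process_jacobian(x, u0, dt)
  want <- diag(9); want[1:3, 4:6] <- diag(3) * dt
  expect_equal(Fx, want)

  set.seed(21)
  for (i in 1:20) {
    x <- random_state(2)
    u <- list(a = matrix(stats::rnorm(6, sd = 4), 2),
              w = matrix(stats::rnorm(6, sd = 2), 2))
    Fa <- process_jacobian(x, u, dt)
    Fn <- fd_process_jacobian(x, u, dt, noise)
    expect_lt(max(abs(Fa - Fn)) / max(abs(Fn)), 1e-5)
  }

  truth <- fixture_truth(10)
  x7 <- erkf_state(truth_initial_state(truth))
  u7 <- list(a = matrix(stats::rnorm(21), 7), w = matrix(stats::rnorm(21), 7))
  F7 <- process_jacobian(x7, u7, dt)
  expect_equal(dim(F7), c(63, 63))
  for (j1 in 1:7) for (j2 in 1:7) {
    blk <- F7[9 * (j1 - 1) + 1:9, 9 * (j2 - 1) + 1:9]
    if (j1 == j2) expect_gt(sum(abs(blk)), 0) else
      expect_equal(blk, matrix(0, 9, 9))
  }
})

test_that("covariance prediction: Q structure, monotone trace, PSD clamping", {
  n <- 2
  x <- random_state(n)
  P0 <- matrix(0, 9 * n, 9 * n)
  dt <- 1 / 128
  P1 <- predict_covariance(P0, diag(9 * n), noise, dt)
  qd <- rep(c(rep(0, 3), rep(noise$sigma_a^2 * dt^2, 3),
              rep(noise$sigma_omega^2 * dt^2, 3)), n)
  expect_equal(P1, diag(qd))
  # position block of Q is exactly zero
  expect_equal(diag(P1)[1:3], c(0, 0, 0))

  set.seed(22)
  P <- crossprod(matrix(stats::rnorm(18 * 18), 18))
  P2 <- predict_covariance(P, diag(18), noise, dt)
  expect_gte(sum(diag(P2)), sum(diag(P)))

  Pbad <- diag(18); Pbad[1, 1] <- -1
  expect_warning(predict_covariance(Pbad, diag(18), noise, dt), "clamping")
})

test_that("ZUPT event: innovation, near-zero post-update velocity, Jacobian oracle", {
  set.seed(23)
  x <- random_state(1)
  x$v[1, ] <- c(0.3, 0, 0)
  ev <- make_zupt("foot_l", noise)
  mm <- measurement_model(ev, x)
  expect_equal(mm$z - mm$h, c(-0.3, 0, 0))

  # with tiny measurement noise the update zeroes the foot velocity
  tiny <- noise_config(sigma_zv = 1e-6)
  up <- batch_update(x, diag(9) * 0.1, list(make_zupt("foot_l", tiny)))
  expect_lt(sqrt(sum(up$x$v[1, ]^2)), 1e-3)

  for (i in 1:20) {
    x <- random_state(2)
    ev <- make_zupt("foot_l", noise)
    expect_lt(max(abs(measurement_model(ev, x)$H -
                        fd_measurement_jacobian(ev, x))), 1e-6)
  }
  expect_error(make_zupt("pelvis", noise), "foot")
})

test_that("tilt event: zero innovation at level attitude, gating, convergence, Jacobian oracle", {
  x <- erkf_state(list(pelvis = list(p = rep(0, 3), v = rep(0, 3),
                                     q = c(1, 0, 0, 0))))
  ev <- make_tilt("pelvis", c(0, 0, 9.81), noise)
  mm <- measurement_model(ev, x)
  expect_equal(mm$z - mm$h, c(0, 0, 0), tolerance = 1e-12)

  # magnitude gate: dynamic contamination suppressed
  expect_null(make_tilt("pelvis", c(0, 0, 5), noise))
  expect_null(make_tilt("pelvis", c(0, 0, 13), noise))

  # repeated still updates monotonically reduce a 10-degree roll error
  xt <- x
  xt$q[1, ] <- rotvec_to_quat(c(10 * pi / 180, 0, 0))
  P <- initial_covariance("pelvis", sigma_th0_deg = 10)
  errs <- numeric(20)
  for (k in 1:20) {
    # true attitude is level, so gravity reaction is +9.81 z in world = body
    a_body <- quat_rotate(quat_conjugate(c(1, 0, 0, 0)), c(0, 0, 9.81))
    up <- batch_update(xt, P, list(make_tilt("pelvis", a_body, noise)))
    xt <- up$x; P <- up$P
    errs[k] <- sqrt(sum(quat_to_rotvec(xt$q[1, ])^2))
  }
  expect_true(all(diff(errs) < 1e-12))
  expect_lt(errs[20], 2 * pi / 180)

  set.seed(24)
  for (i in 1:20) {
    x <- random_state(2)
    ev <- make_tilt("foot_l", quat_rotate(quat_conjugate(x$q[1, ]),
                                          c(0, 0, 9.81)), noise)
    expect_lt(max(abs(measurement_model(ev, x)$H -
                        fd_measurement_jacobian(ev, x))), 1e-6)
  }
})

test_that("joint-center event: geometric consistency, offset response, Jacobian oracle", {
  set.seed(25)
  # two IMUs placed consistently about a shared joint center
  c_w <- c(0.3, -0.2, 0.9)
  q1 <- quat_normalize(stats::rnorm(4)); q2 <- quat_normalize(stats::rnorm(4))
  r1 <- c(0.1, 0.05, -0.02); r2 <- c(-0.08, 0.12, 0.03)
  x <- erkf_state(list(
    thigh_l = list(p = c_w - quat_rotate(q1, r1), v = rep(0, 3), q = q1),
    shank_l = list(p = c_w - quat_rotate(q2, r2), v = rep(0, 3), q = q2)))
  ev <- make_joint_center("thigh_l", "shank_l", r1, r2, noise)
  mm <- measurement_model(ev, x)
  expect_equal(mm$z - mm$h, c(0, 0, 0), tolerance = 1e-12)

  x$p[2, ] <- x$p[2, ] + c(0, 0, 0.01)
  mm <- measurement_model(ev, x)
  expect_equal(mm$z - mm$h, c(0, 0, 0.01), tolerance = 1e-12)

  for (i in 1:20) {
    x <- random_state(2)
    ev <- make_joint_center("foot_l", "foot_r", stats::rnorm(3, sd = 0.1),
                            stats::rnorm(3, sd = 0.1), noise)
    expect_lt(max(abs(measurement_model(ev, x)$H -
                        fd_measurement_jacobian(ev, x))), 1e-6)
  }
  expect_error(make_joint_center("foot_l", "foot_l", r1, r2, noise),
               "distinct")
})

test_that("joint-axis event: alignment, chord-length innovation, Jacobian oracle", {
  e1 <- c(0, 0, 1)
  x <- erkf_state(list(
    thigh_l = list(p = rep(0, 3), v = rep(0, 3), q = c(1, 0, 0, 0)),
    shank_l = list(p = rep(0, 3), v = rep(0, 3), q = c(1, 0, 0, 0))))
  ev <- make_joint_axis("thigh_l", "shank_l", e1, e1, noise$sigma_ja_knee)
  expect_equal(measurement_model(ev, x)$h, c(0, 0, 0))

  # 5-degree relative rotation about an axis perpendicular to e gives
  # innovation norm 2 sin(2.5 deg)
  x$q[2, ] <- rotvec_to_quat(c(5 * pi / 180, 0, 0))
  h <- measurement_model(ev, x)$h
  expect_equal(sqrt(sum(h^2)), 2 * sin(2.5 * pi / 180), tolerance = 1e-9)

  set.seed(26)
  for (i in 1:20) {
    x <- random_state(2)
    e1 <- quat_normalize(stats::rnorm(4))[2:4]; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- stats::rnorm(3); e2 <- e2 / sqrt(sum(e2^2))
    ev <- make_joint_axis("foot_l", "foot_r", e1, e2, noise$sigma_ja_hip)
    expect_lt(max(abs(measurement_model(ev, x)$H -
                        fd_measurement_jacobian(ev, x))), 1e-6)
  }
  expect_error(make_joint_axis("foot_l", "foot_r", c(1, 1, 0), c(1, 0, 0), 1),
               "unit")
})

test_that("batch update reproduces the scalar Kalman closed form for a single ZUPT", {
  # 1-IMU system, diagonal P: the ZUPT row for each velocity axis is an
  # independent scalar Kalman update v' = v - P v / (P + C)
  p0 <- 0.04; c0 <- noise$sigma_zv^2
  x <- erkf_state(list(foot_l = list(p = c(1, 2, 3), v = c(0.3, -0.1, 0.2),
                                     q = c(1, 0, 0, 0))))
  P <- diag(rep(c(0.01, p0, 0.001), each = 3))
  up <- batch_update(x, P, list(make_zupt("foot_l", noise)))
  k <- p0 / (p0 + c0)
  expect_equal(up$x$v[1, ], c(0.3, -0.1, 0.2) * (1 - k), tolerance = 1e-8)
  expect_equal(diag(up$P)[4:6], rep(p0 * (1 - k), 3), tolerance = 1e-10)
  # position and attitude untouched by a pure velocity measurement
  expect_equal(up$x$p[1, ], c(1, 2, 3))
  expect_error(batch_update(x, P, list()), "pass-through")
})

test_that("covariance stays symmetric PSD through fuzzed predict/update cycles", {
  set.seed(27)
  x <- random_state(2)
  P <- initial_covariance(x$imus)
  dt <- 1 / 128
  for (k in 1:500) {
    u <- list(a = matrix(stats::rnorm(6, sd = 5), 2),
              w = matrix(stats::rnorm(6, sd = 3), 2))
    Fx <- process_jacobian(x, u, dt)
    x <- predict_state(x, u, dt, noise)
    P <- predict_covariance(P, Fx, noise, dt, check = FALSE)
    evs <- list(make_joint_center("foot_l", "foot_r",
                                  stats::rnorm(3, sd = 0.1),
                                  stats::rnorm(3, sd = 0.1), noise))
    if (k %% 3 == 0) evs <- c(evs, list(make_zupt("foot_l", noise)))
    up <- batch_update(x, P, evs)
    x <- up$x; P <- up$P
    expect_lt(max(abs(P - t(P))), 1e-9)
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("prediction-only filtering equals raw strapdown integration bit-for-bit", {
  truth <- fixture_truth(10)
  imu <- fixture_imu(10, noisy = TRUE)
  sub <- imu[imu$t <= 3, ]
  fit <- run_erkf(sub, truth$calibration, truth_initial_state(truth),
                  corrections = correction_config(FALSE, FALSE, FALSE, FALSE))
  # manual strapdown over the same samples
  x <- erkf_state(truth_initial_state(truth))
  streams <- lapply(stats::setNames(x$imus, x$imus), function(nm) {
    d <- sub[sub$imu == nm, ]
    list(a = cbind(d$ax, d$ay, d$az), w = cbind(d$gx, d$gy, d$gz))
  })
  N <- sum(sub$imu == "pelvis")
  for (k in seq_len(N - 1)) {
    u <- list(a = do.call(rbind, lapply(streams, function(s) s$a[k, ])),
              w = do.call(rbind, lapply(streams, function(s) s$w[k, ])))
    x <- predict_state(x, u, 1 / 128, noise_config())
  }
  last <- fit$poses[fit$poses$t == max(fit$poses$t), ]
  for (j in seq_along(x$imus)) {
    row <- last[last$imu == x$imus[j], ]
    expect_identical(c(row$px, row$py, row$pz), unname(x$p[j, ]))
    expect_identical(c(row$qw, row$qx, row$qy, row$qz), unname(x$q[j, ]))
  }
})

test_that("the filter aborts informatively on non-finite states", {
  truth <- fixture_truth(10)
  imu <- fixture_imu(10)
  bad <- imu
  bad$ax[500] <- NaN
  expect_error(run_erkf(bad[bad$t <= 5, ], truth$calibration,
                        truth_initial_state(truth)),
               "non-finite")
})
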
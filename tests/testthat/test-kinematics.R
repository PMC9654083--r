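test_that("segment_orientation composes and round-trips mounting rotations", {
  set.seed(41)
  q <- quat_normalize(stats::rnorm(4))
  expect_equal(segment_orientation(q, diag(3)), quat_to_matrix(q))
  R_as <- rodrigues(c(0, 0, 30 * pi / 180))
  R_wa <- segment_orientation(q, R_as)
  # segment -> IMU -> segment is the identity
  expect_equal(R_wa %*% t(R_as) %*% R_as, R_wa, tolerance = 1e-12)
  expect_equal(t(quat_to_matrix(q)) %*% R_wa, R_as, tolerance = 1e-12)
  expect_error(segment_orientation(q, matrix(1, 3, 3)), "orthonormal")

  # a known 30-degree mounting rotation is recovered exactly on simulator truth
  truth <- fixture_truth(10)
  cal <- truth$calibration
  nm <- "thigh_l"
  k <- 100
  q_ws <- truth$streams[[nm]]$q[k, ]
  R_wa <- segment_orientation(q_ws, cal$imus[[nm]]$R_as)
  # reconstruct R_as from the known anatomical orientation: R_as = R_ws^T R_wa
  expect_equal(t(quat_to_matrix(q_ws)) %*% R_wa, cal$imus[[nm]]$R_as,
               tolerance = 1e-12)
})

test_that("Z-X-Y decomposition: identity, single-axis, compose-decompose oracle", {
  expect_equal(unname(joint_angles(diag(3), diag(3))), c(0, 0, 0))
  R30 <- rodrigues(c(0, 0, 30 * pi / 180))
  expect_equal(unname(joint_angles(diag(3), R30)), c(30, 0, 0),
               tolerance = 1e-12)
  a <- joint_angles(diag(3), joint_angle_matrix(20, 5, 10))
  expect_equal(unname(a), c(20, 5, 10), tolerance = 1e-9)

  # property: decomposition inverts composition away from gimbal lock,
  # on both sides
  set.seed(42)
  for (i in 1:100) {
    fe <- stats::runif(1, -120, 120)
    ab <- stats::runif(1, -45, 45)
    ie <- stats::runif(1, -45, 45)
    side <- sample(c("l", "r"), 1)
    Rp <- rodrigues(stats::rnorm(3))
    Rrel <- joint_angle_matrix(fe, ab, ie, side)
    got <- joint_angles(Rp, Rp %*% Rrel, side = side)
    expect_equal(unname(got), c(fe, ab, ie), tolerance = 1e-9)
  }
  expect_warning(joint_angles(diag(3), joint_angle_matrix(0, 90, 0)),
                 "gimbal")
})

test_that("truth joint angles equal the kinematics-layer decomposition of truth poses", {
  truth <- fixture_truth(10)
  ang <- estimate_joint_angles(truth, truth$calibration, lowpass = FALSE)
  j <- dplyr::inner_join(ang, truth$angles, by = c("t", "joint", "side"),
                         suffix = c("_k", "_t"))
  expect_gt(nrow(j), 1000)
  expect_lt(max(abs(j$fe_k - j$fe_t)), 1e-9)
  expect_lt(max(abs(j$abad_k - j$abad_t)), 1e-9)
  expect_lt(max(abs(j$ie_k - j$ie_t)), 1e-9)
  # the simulated knee is an exact hinge: out-of-plane knee angles vanish
  kn <- ang[ang$joint == "knee", ]
  expect_lt(max(abs(kn$abad)), 1e-8)
  expect_lt(max(abs(kn$ie)), 1e-8)
})

test_that("zero-lag filter: DC unity, passband preservation, stopband attenuation", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  expect_equal(lowpass_zero_lag(rep(2.5, length(t)), 6, fs), rep(2.5, length(t)),
               tolerance = 1e-9)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_zero_lag(s1, 6, fs)
  mid <- t > 2 & t < 8
  expect_lt(max(abs(f1[mid] - s1[mid])), 0.01)
  s30 <- sin(2 * pi * 30 * t)
  f30 <- lowpass_zero_lag(s30, 6, fs)
  expect_lt(max(abs(f30[mid])), 10^(-20 / 20))
  # -3 dB of the two-pass response sits at the nominal cutoff
  s6 <- sin(2 * pi * 6 * t)
  f6 <- lowpass_zero_lag(s6, 6, fs)
  amp <- max(abs(f6[mid]))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.02)
  # NA gaps: short segments are dropped with a message, long ones filtered
  x <- c(s1[1:10], NA, s1)
  expect_message(out <- lowpass_zero_lag(x, 6, fs), "skipped")
  expect_true(all(is.na(out[1:11])))
  expect_false(anyNA(out[-(1:11)]))
})

test_that("per-stride ROM: basic values, NA handling, 30% suppression rule, offset invariance", {
  fs <- 128
  ffs <- tibble::tibble(foot = "foot_r", t = 0:10, index = 0:10 * fs + 1L)
  t <- seq(0, 10, by = 1 / fs)
  saw <- 10 + 40 * abs(2 * ((t %% 1) - 0.5)) # 50 -> 10 -> 50 sawtooth per 1 s
  ang <- tibble::tibble(t = t, joint = "knee", side = "r",
                        fe = saw, abad = 0 * t + 5, ie = 0 * t)
  rom <- range_of_motion(ang, ffs)
  expect_equal(nrow(rom), 30) # 10 strides x 3 angles
  expect_equal(rom$rom[rom$angle == "fe"], rep(40, 10), tolerance = 1e-10)
  expect_equal(rom$rom[rom$angle == "abad"], rep(0, 10))

  # NaN contamination invalidates exactly the affected strides; > 30% of
  # strides invalid suppresses the trial summary
  ang_bad <- ang
  ang_bad$fe[ang_bad$t > 1 & ang_bad$t < 5] <- NaN # strides 2-5 of 10
  rom_bad <- range_of_motion(ang_bad, ffs)
  fe_bad <- rom_bad[rom_bad$angle == "fe", ]
  expect_equal(sum(fe_bad$valid), 6)
  rs <- rom_summary(rom_bad)
  expect_true(rs$suppressed[rs$angle == "fe"])
  expect_true(is.na(rs$mean[rs$angle == "fe"]))
  expect_false(rs$suppressed[rs$angle == "abad"])

  # ROM is invariant to constant offsets
  ang_off <- ang
  ang_off$fe <- ang_off$fe + 37.3
  expect_equal(range_of_motion(ang_off, ffs)$rom, rom$rom, tolerance = 1e-10)

  expect_equal(nrow(range_of_motion(ang, ffs[1, ])), 0)
})

test_that("heel trajectory: offset composition and truth recovery", {
  truth <- fixture_truth(10)
  # zero offset reduces to the IMU position
  cal0 <- truth$calibration
  cal0$heel$foot_l <- c(0, 0, 0)
  h0 <- heel_trajectory(truth, cal0)
  d <- h0[h0$foot == "foot_l", ]
  expect_equal(cbind(d$x, d$y, d$z), unname(truth$streams$foot_l$p),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant offset with identity attitude shifts by exactly the offset
  pose <- tibble::tibble(t = 0:1, imu = "foot_l", px = 0, py = 0, pz = 0,
                         qw = 1, qx = 0, qy = 0, qz = 0)
  cal1 <- truth$calibration
  cal1$heel <- list(foot_l = c(0.1, 0, 0))
  h1 <- heel_trajectory(pose, cal1)
  expect_equal(c(h1$x[1], h1$y[1], h1$z[1]), c(0.1, 0, 0))
  # the packaged heel path of truth matches recomputation (< 1 mm)
  h <- heel_trajectory(truth, truth$calibration)
  j <- dplyr::inner_join(h, truth$heel, by = c("t", "foot"),
                         suffix = c("_k", "_t"))
  expect_lt(max(abs(cbind(j$x_k - j$x_t, j$y_k - j$y_t, j$z_k - j$z_t))),
            1e-3)
})

test_that("stride metrics reproduce the hand geometry of the definitions", {
  fs <- 10
  mk_heel <- function(foot, xy) {
    tibble::tibble(t = seq(0, by = 0.1, length.out = nrow(xy)), foot = foot,
                   x = xy[, 1], y = xy[, 2], z = 0)
  }
  # right footfalls at (0,0) and (1,0); intermediate left at (0.5, 0.12)
  hr <- mk_heel("foot_r", cbind(seq(0, 1, length.out = 21), 0))
  hl <- mk_heel("foot_l", cbind(seq(0, 1, length.out = 21), 0.12))
  ff <- tibble::tibble(foot = c("foot_r", "foot_l", "foot_r"),
                       t = c(0, 1, 2), index = c(1L, 11L, 21L))
  s <- stride_metrics(dplyr::bind_rows(hr, hl), ff, drop_transition = FALSE)
  expect_equal(s$sl, 1)
  expect_equal(s$sw, 0.12)

  # collinear lateral-walking geometry: step width 0
  hl2 <- mk_heel("foot_l", cbind(seq(0, 1, length.out = 21), 0))
  s2 <- stride_metrics(dplyr::bind_rows(hr, hl2), ff, drop_transition = FALSE)
  expect_equal(s2$sl, 1)
  expect_equal(s2$sw, 0)

  # purely vertical displacement: stride length 0
  hv <- mk_heel("foot_r", cbind(rep(0, 21), 0))
  hv$z <- seq(0, 0.5, length.out = 21)
  s3 <- stride_metrics(dplyr::bind_rows(hv, hl), ff, drop_transition = FALSE)
  expect_equal(s3$sl, 0)

  # no intermediate opposite footfall: sw is NA
  ff2 <- tibble::tibble(foot = c("foot_r", "foot_r"), t = c(0, 2),
                        index = c(1L, 21L))
  s4 <- stride_metrics(dplyr::bind_rows(hr, hl), ff2, drop_transition = FALSE)
  expect_true(is.na(s4$sw))
})

test_that("stride metrics are invariant to horizontal rigid motions and drop transition strides", {
  truth <- fixture_truth(20)
  s <- stride_metrics(truth$heel, truth$footfalls)
  # transition strides dropped: first and last two per foot
  n_ff_l <- sum(truth$footfalls$foot == "foot_l")
  expect_equal(sum(s$foot == "foot_l"), n_ff_l - 1 - 3)
  expect_false(1 %in% s$stride[s$foot == "foot_l"])

  # rotate about z and translate in the plane: SL and SW unchanged
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  hr <- truth$heel
  xy <- t(Rz %*% t(cbind(hr$x, hr$y))) + matrix(c(3, -2), nrow(hr), 2,
                                                byrow = TRUE)
  hr$x <- xy[, 1]; hr$y <- xy[, 2]
  s2 <- stride_metrics(hr, truth$footfalls)
  expect_equal(s2$sl, s$sl, tolerance = 1e-12)
  expect_equal(s2$sw, s$sw, tolerance = 1e-12)
})
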
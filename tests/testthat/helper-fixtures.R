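# Shared fixtures (built once per test run) and finite-difference oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture_truth <- function(duration = 10, gait_type = "forward_normal") {
  key <- paste0("truth_", gait_type, "_", duration)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_gait(gait_spec(gait_type,
                                                   duration = duration))
  }
  .fixture_env[[key]]
}

fixture_imu <- function(duration = 10, gait_type = "forward_normal",
                        noisy = FALSE, seed = 7) {
  key <- paste0("imu_", gait_type, "_", duration, "_", noisy, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    truth <- fixture_truth(duration, gait_type)
    .fixture_env[[key]] <- synthesize_imu(
      truth, noise = if (noisy) noise_config() else NULL, seed = seed)
  }
  .fixture_env[[key]]
}

# random multi-IMU state; names chosen so ZUPT targets exist
random_state <- function(n_imu = 2) {
  nm <- c("foot_l", "foot_r", "pelvis", "thigh_l", "shank_l", "thigh_r",
          "shank_r")[seq_len(n_imu)]
  x0 <- lapply(seq_len(n_imu), function(j)
    list(p = stats::rnorm(3), v = stats::rnorm(3),
         q = quat_normalize(stats::rnorm(4))))
  names(x0) <- nm
  erkf_state(x0)
}

# apply an error-state perturbation (right-multiplicative on attitude)
perturb_state <- function(x, dx) {
  for (j in seq_along(x$imus)) {
    b <- 9 * (j - 1)
    x$p[j, ] <- x$p[j, ] + dx[b + 1:3]
    x$v[j, ] <- x$v[j, ] + dx[b + 4:6]
    x$q[j, ] <- quat_multiply(x$q[j, ], rotvec_to_quat(dx[b + 7:9]))
  }
  x
}

# error-state difference between two states: xb "minus" xa
state_diff <- function(xb, xa) {
  out <- numeric(9 * length(xa$imus))
  for (j in seq_along(xa$imus)) {
    b <- 9 * (j - 1)
    out[b + 1:3] <- xb$p[j, ] - xa$p[j, ]
    out[b + 4:6] <- xb$v[j, ] - xa$v[j, ]
    out[b + 7:9] <- quat_to_rotvec(quat_multiply(quat_conjugate(xa$q[j, ]),
                                                 xb$q[j, ]))
  }
  out
}

# central finite-difference Jacobian of the process model w.r.t. the error state
fd_process_jacobian <- function(x, u, dt, noise, eps = 1e-6) {
  nd <- 9 * length(x$imus)
  J <- matrix(0, nd, nd)
  f0 <- predict_state(x, u, dt, noise)
  for (i in seq_len(nd)) {
    e <- numeric(nd); e[i] <- eps
    fp <- predict_state(perturb_state(x, e), u, dt, noise)
    fm <- predict_state(perturb_state(x, -e), u, dt, noise)
    J[, i] <- state_diff(fp, fm) / (2 * eps)
  }
  J
}

# central finite-difference Jacobian of a measurement event
fd_measurement_jacobian <- function(event, x, eps = 1e-6) {
  nd <- 9 * length(x$imus)
  J <- matrix(0, 3, nd)
  for (i in seq_len(nd)) {
    e <- numeric(nd); e[i] <- eps
    hp <- measurement_model(event, perturb_state(x, e))$h
    hm <- measurement_model(event, perturb_state(x, -e))$h
    J[, i] <- (hp - hm) / (2 * eps)
  }
  J
}

expect_rel_close <- function(got, want, rel_tol, scale = NULL) {
  s <- scale %||% max(abs(want), 1)
  expect_lt(max(abs(got - want)) / s, rel_tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
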
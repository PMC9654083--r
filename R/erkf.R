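#' Noise configuration for the error-state filter
#'
#' Process noise densities for the accelerometer and gyroscope and
#' measurement noises for the four correction models. Defaults are typical
#' IMU-grade values at a 128 Hz sampling rate; angular quantities are given
#' in degrees for readability and converted to radians here, filter-internal
#' units are SI throughout. The hip joint-axis noise is deliberately a
#' factor ~50 larger than the knee's: the hip correction is a "soft" hinge
#' that only nudges the flexion axes of pelvis and thigh towards alignment,
#' whereas the knee is nearly hinge-like during gait.
#'
#' @param sigma_a accelerometer noise, m/s^2.
#' @param sigma_omega_deg gyroscope noise, deg/s.
#' @param sigma_zv zero-velocity measurement noise, m/s.
#' @param sigma_tilt_deg gravitational tilt noise, deg.
#' @param sigma_jc joint-center noise, m.
#' @param sigma_ja_knee_deg knee joint-axis noise, deg.
#' @param sigma_ja_hip_deg hip joint-axis noise, deg.
#' @param g gravitational acceleration in the world frame, m/s^2.
#' @return a `noise_config` list with all angles in radians.
#' @export
noise_config <- function(sigma_a = 0.013, sigma_omega_deg = 2.83,
                         sigma_zv = 0.01, sigma_tilt_deg = 5.73,
                         sigma_jc = 0.01, sigma_ja_knee_deg = 1.15,
                         sigma_ja_hip_deg = 57.3,
                         g = c(0, 0, -9.81)) {
  cfg <- list(sigma_a = sigma_a, sigma_omega = sigma_omega_deg * pi / 180,
              sigma_zv = sigma_zv, sigma_tilt = sigma_tilt_deg * pi / 180,
              sigma_jc = sigma_jc,
              sigma_ja_knee = sigma_ja_knee_deg * pi / 180,
              sigma_ja_hip = sigma_ja_hip_deg * pi / 180,
              g = g)
  sig <- unlist(cfg[startsWith(names(cfg), "sigma")])
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all noise sigmas must be finite and > 0", call. = FALSE)
  structure(cfg, class = "noise_config")
}

#' Nominal multi-IMU state
#'
#' The nominal state stacks position (m), velocity (m/s) and a unit
#' quaternion per IMU. The companion error state (not stored; its mean is
#' identically zero between updates) stacks `[dp, dv, dtheta]` per IMU in
#' the same order, with the attitude error applied right-multiplicatively:
#' `q <- q (x) exp(dtheta)`.
#'
#' @param x0 named list of per-IMU poses, each with fields `p`, `v`
#'   (length 3) and `q` (unit quaternion), e.g. [truth_initial_state()].
#' @return an `erkf_state` with matrix fields `p`, `v` (n x 3), `q`
#'   (n x 4) and the IMU names.
#' @export
erkf_state <- function(x0) {
  nm <- names(x0)
  if (is.null(nm) || any(nm == "")) stop("x0 must be a named list", call. = FALSE)
  p <- t(vapply(x0, function(s) s$p, numeric(3)))
  v <- t(vapply(x0, function(s) s$v, numeric(3)))
  q <- t(vapply(x0, function(s) quat_normalize(s$q), numeric(4)))
  .check_finite(cbind(p, v, q), "initial state")
  structure(list(p = p, v = v, q = q, imus = nm), class = "erkf_state")
}

#' @export
print.erkf_state <- function(x, ...) {
  cat("<erkf_state>", length(x$imus), "IMUs:", paste(x$imus, collapse = ", "), "\n")
  invisible(x)
}

state_dim <- function(x) 9L * length(x$imus)

err_idx <- function(x, imu) {
  j <- match(imu, x$imus)
  if (is.na(j)) stop("unknown IMU: ", imu, call. = FALSE)
  list(p = 9L * (j - 1L) + 1:3, v = 9L * (j - 1L) + 4:6,
       th = 9L * (j - 1L) + 7:9)
}

#' Strapdown prediction of the nominal state
#'
#' One step of strapdown integration per IMU, each IMU independent:
#' `p <- p + v dt + (R a + g) dt^2 / 2`, `v <- v + (R a + g) dt`,
#' `q <- q (x) exp(omega dt)`.
#'
#' @param x an `erkf_state`.
#' @param u IMU samples: list with matrices `a`, `w` (n_imu x 3; specific
#'   force m/s^2 and angular rate rad/s, sensor frame), rows in the order of
#'   `x$imus`.
#' @param dt sampling period, s.
#' @param noise a [noise_config()] (supplies the gravity vector).
#' @return the predicted `erkf_state`.
#' @export
predict_state <- function(x, u, dt, noise = noise_config()) {
  stopifnot(inherits(x, "erkf_state"), dt > 0)
  n <- length(x$imus)
  for (j in seq_len(n)) {
    if (!all(is.finite(c(u$a[j, ], u$w[j, ]))))
      stop("non-finite IMU sample for IMU ", j, call. = FALSE)
    acc <- quat_rotate(x$q[j, ], u$a[j, ]) + noise$g
    x$p[j, ] <- x$p[j, ] + x$v[j, ] * dt + 0.5 * acc * dt^2
    x$v[j, ] <- x$v[j, ] + acc * dt
    x$q[j, ] <- quat_multiply(x$q[j, ], rotvec_to_quat(u$w[j, ] * dt))
  }
  x
}

#' Jacobian of the process model with respect to the error state
#'
#' Block-diagonal over IMUs; each 9x9 block is
#' `[[I, dt I, -R [a]_x dt^2/2], [0, I, -R [a]_x dt], [0, 0, S(omega dt)^T]]`
#' with `S` the Rodrigues rotation matrix, evaluated at the pre-prediction
#' state. This is the exact Jacobian of the strapdown map under the
#' right-multiplicative attitude-error convention; the `dt^2/2`
#' position-attitude coupling (often truncated to zero in ErKF
#' formulations) is retained so the Jacobian matches finite differences of
#' [predict_state()] to first order in the perturbation.
#'
#' @inheritParams predict_state
#' @return a `9n x 9n` matrix.
#' @export
process_jacobian <- function(x, u, dt) {
  n <- length(x$imus)
  Fx <- diag(9L * n)
  for (j in seq_len(n)) {
    b <- 9L * (j - 1L)
    R <- quat_to_matrix(x$q[j, ])
    RaX <- R %*% skew(u$a[j, ])
    Fx[b + 1:3, b + 4:6] <- diag(3) * dt
    Fx[b + 1:3, b + 7:9] <- -RaX * dt^2 / 2
    Fx[b + 4:6, b + 7:9] <- -RaX * dt
    Fx[b + 7:9, b + 7:9] <- t(rodrigues(u$w[j, ] * dt))
  }
  Fx
}

process_noise_diag <- function(n_imu, noise, dt) {
  rep(c(rep(0, 3), rep(noise$sigma_a^2 * dt^2, 3),
        rep(noise$sigma_omega^2 * dt^2, 3)), n_imu)
}

#' Covariance prediction
#'
#' `P <- Fx P Fx^T + Q` with `Q` block-diagonal per IMU: zeros on the
#' position block and `sigma^2 dt^2 I` on the velocity and attitude blocks.
#' The result is symmetrised. A non-PSD input triggers a warning and
#' eigenvalue clamping at -1e-10.
#'
#' @param P error covariance, `9n x 9n`.
#' @param Fx process Jacobian from [process_jacobian()].
#' @param noise a [noise_config()].
#' @param dt sampling period, s.
#' @param check if `TRUE`, verify positive semidefiniteness of the input.
#' @return the predicted, symmetrised covariance.
#' @export
predict_covariance <- function(P, Fx, noise, dt, check = TRUE) {
  stopifnot(nrow(P) == ncol(P), nrow(Fx) == nrow(P))
  if (check) {
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      warning("covariance not PSD (min eigenvalue ", format(min(ev)),
              "); clamping")
      e <- eigen(P, symmetric = TRUE)
      P <- e$vectors %*% (pmax(e$values, -1e-10) * t(e$vectors))
    }
  }
  P <- Fx %*% P %*% t(Fx)
  diag(P) <- diag(P) + process_noise_diag(nrow(P) / 9L, noise, dt)
  (P + t(P)) / 2
}

#' Default initial error covariance
#'
#' @param imus character vector of IMU names.
#' @param sigma_p0,sigma_v0 initial position / velocity uncertainty (m, m/s).
#' @param sigma_th0_deg initial attitude uncertainty, deg.
#' @return diagonal `9n x 9n` matrix.
#' @export
initial_covariance <- function(imus, sigma_p0 = 0.01, sigma_v0 = 0.01,
                               sigma_th0_deg = 1) {
  diag(rep(c(rep(sigma_p0^2, 3), rep(sigma_v0^2, 3),
             rep((sigma_th0_deg * pi / 180)^2, 3)), length(imus)))
}

# ---- measurement events -----------------------------------------------------

new_event <- function(kind, imus, z, C, payload = NULL) {
  structure(list(kind = kind, imus = imus, z = z, C = C, payload = payload),
            class = "erkf_event")
}

#' Measurement events
#'
#' Constructors for the four correction measurements. Each returns an
#' `erkf_event` carrying the observed measurement `z`, its noise covariance
#' `C` and the payload needed to evaluate the expected measurement; the
#' state-dependent `h(x)` and Jacobian come from [measurement_model()].
#'
#' * `make_zupt`: the foot IMU velocity is observed to be zero while the
#'   foot is planted.
#' * `make_tilt`: a still IMU's accelerometer direction observes gravity;
#'   the event is suppressed (returns `NULL`) when the measured magnitude
#'   falls outside `[0.8, 1.2] |g|`, rejecting dynamic contamination.
#' * `make_joint_center`: the world-resolved joint center computed from the
#'   two adjacent IMUs must coincide.
#' * `make_joint_axis`: the flexion axes of the two adjacent segments,
#'   resolved in the world frame, are observed to align (a soft hinge).
#'   No joint-axis event is used at the ankle.
#'
#' @param imu,imu1,imu2 IMU names.
#' @param noise a [noise_config()].
#' @param a_meas measured specific force (length 3, m/s^2).
#' @param r1,r2 joint-center offsets in each IMU frame, m.
#' @param e1,e2 unit joint-axis vectors in each IMU frame.
#' @param sigma_ja joint-axis noise, rad (knee or hip value).
#' @return an `erkf_event`, or `NULL` for a suppressed tilt.
#' @name measurement-events
NULL

#' @rdname measurement-events
#' @export
make_zupt <- function(imu, noise) {
  if (!grepl("^foot", imu))
    stop("ZUPT events apply to foot IMUs only, got: ", imu, call. = FALSE)
  new_event("ZUPT", imu, z = c(0, 0, 0), C = diag(3) * noise$sigma_zv^2)
}

#' @rdname measurement-events
#' @export
make_tilt <- function(imu, a_meas, noise) {
  na <- sqrt(sum(a_meas^2))
  if (na == 0) stop("zero accelerometer vector", call. = FALSE)
  gmag <- sqrt(sum(noise$g^2))
  if (na < 0.8 * gmag || na > 1.2 * gmag) return(NULL)
  new_event("TILT", imu, z = a_meas / na, C = diag(3) * noise$sigma_tilt^2)
}

#' @rdname measurement-events
#' @export
make_joint_center <- function(imu1, imu2, r1, r2, noise) {
  if (identical(imu1, imu2)) stop("joint connects two distinct IMUs", call. = FALSE)
  new_event("JOINT_CENTER", c(imu1, imu2), z = c(0, 0, 0),
            C = diag(3) * noise$sigma_jc^2, payload = list(r1 = r1, r2 = r2))
}

#' @rdname measurement-events
#' @export
make_joint_axis <- function(imu1, imu2, e1, e2, sigma_ja) {
  if (identical(imu1, imu2)) stop("joint connects two distinct IMUs", call. = FALSE)
  if (abs(sqrt(sum(e1^2)) - 1) > 1e-6 || abs(sqrt(sum(e2^2)) - 1) > 1e-6)
    stop("joint axes must be unit vectors", call. = FALSE)
  new_event("JOINT_AXIS", c(imu1, imu2), z = c(0, 0, 0),
            C = diag(3) * sigma_ja^2, payload = list(e1 = e1, e2 = e2))
}

#' Expected measurement and error-state Jacobian of an event
#'
#' Evaluates `h(x)` and the 3 x 9n Jacobian `H` of an event at a state,
#' under the right-multiplicative attitude-error convention
#' (`q <- q (x) exp(dtheta)`), so e.g. a world-resolved lever arm `R r`
#' perturbs as `-R [r]_x dtheta`.
#'
#' @param event an `erkf_event`.
#' @param x an `erkf_state`.
#' @param Rlist optional precomputed list of per-IMU rotation matrices.
#' @return list with `z`, `h`, `H`, `C`.
#' @export
measurement_model <- function(event, x, Rlist = NULL) {
  nd <- state_dim(x)
  H <- matrix(0, 3, nd)
  getR <- function(imu) {
    if (!is.null(Rlist)) Rlist[[imu]] else quat_to_matrix(x$q[match(imu, x$imus), ])
  }
  if (event$kind == "ZUPT") {
    ix <- err_idx(x, event$imus)
    h <- x$v[match(event$imus, x$imus), ]
    H[, ix$v] <- diag(3)
  } else if (event$kind == "TILT") {
    ix <- err_idx(x, event$imus)
    R <- getR(event$imus)
    h <- drop(t(R) %*% c(0, 0, 1))
    H[, ix$th] <- skew(h)
  } else if (event$kind == "JOINT_CENTER") {
    i1 <- err_idx(x, event$imus[1]); i2 <- err_idx(x, event$imus[2])
    R1 <- getR(event$imus[1]); R2 <- getR(event$imus[2])
    j1 <- match(event$imus[1], x$imus); j2 <- match(event$imus[2], x$imus)
    h <- (x$p[j1, ] + drop(R1 %*% event$payload$r1)) -
      (x$p[j2, ] + drop(R2 %*% event$payload$r2))
    H[, i1$p] <- diag(3)
    H[, i1$th] <- -R1 %*% skew(event$payload$r1)
    H[, i2$p] <- -diag(3)
    H[, i2$th] <- R2 %*% skew(event$payload$r2)
  } else if (event$kind == "JOINT_AXIS") {
    i1 <- err_idx(x, event$imus[1]); i2 <- err_idx(x, event$imus[2])
    R1 <- getR(event$imus[1]); R2 <- getR(event$imus[2])
    h <- drop(R1 %*% event$payload$e1) - drop(R2 %*% event$payload$e2)
    H[, i1$th] <- -R1 %*% skew(event$payload$e1)
    H[, i2$th] <- R2 %*% skew(event$payload$e2)
  } else {
    stop("unknown event kind: ", event$kind, call. = FALSE)
  }
  list(z = event$z, h = h, H = H, C = event$C)
}

#' Batch measurement update with error injection and covariance reset
#'
#' Stacks all events observed at one time step into a single linear update:
#' Kalman gain `K = P H^T (H P H^T + C)^-1` (solved through a symmetric
#' factorisation, never an explicit inverse, with 1e-12 jitter escalation if
#' the innovation covariance is near-singular), error-state mean
#' `dx = K (z - h)`, injection of `dx` into the nominal state (quaternions
#' via the exponential map, with the analytic zero-angle limit), reset of
#' the error mean to zero, and the reset-aware covariance update
#' `P <- G (I - K H) P G^T` where `G` is block-diagonal with
#' `I - [dtheta/2]_x` on the attitude blocks.
#'
#' @param x an `erkf_state` (the predicted state).
#' @param P predicted error covariance.
#' @param events non-empty list of `erkf_event`s.
#' @return list with the updated `x`, `P`, the error-state mean `dx` that
#'   was injected, and `jitter` (TRUE if the innovation solve needed
#'   regularisation).
#' @export
batch_update <- function(x, P, events) {
  events <- events[!vapply(events, is.null, logical(1))]
  if (length(events) == 0) stop("no events; use the pass-through path", call. = FALSE)
  nd <- state_dim(x)
  Rlist <- stats::setNames(lapply(seq_along(x$imus), function(j)
    quat_to_matrix(x$q[j, ])), x$imus)
  mm <- lapply(events, measurement_model, x = x, Rlist = Rlist)
  H <- do.call(rbind, lapply(mm, `[[`, "H"))
  z <- unlist(lapply(mm, `[[`, "z"))
  h <- unlist(lapply(mm, `[[`, "h"))
  Cs <- lapply(mm, `[[`, "C")
  Cdiag <- unlist(lapply(Cs, diag))
  PHt <- P %*% t(H)
  S <- H %*% PHt
  diag(S) <- diag(S) + Cdiag
  S <- (S + t(S)) / 2
  jitter <- FALSE
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- TRUE
    ch <- chol(S + diag(nrow(S)) * 1e-12 * max(diag(S), 1))
  }
  K <- PHt %*% chol2inv(ch)
  dx <- drop(K %*% (z - h))
  # inject the error-state mean into the nominal state
  G <- diag(nd)
  for (j in seq_along(x$imus)) {
    b <- 9L * (j - 1L)
    x$p[j, ] <- x$p[j, ] + dx[b + 1:3]
    x$v[j, ] <- x$v[j, ] + dx[b + 4:6]
    dth <- dx[b + 7:9]
    x$q[j, ] <- quat_multiply(x$q[j, ], rotvec_to_quat(dth))
    G[b + 7:9, b + 7:9] <- diag(3) - skew(dth / 2)
  }
  M <- (diag(nd) - K %*% H) %*% P
  P <- G %*% M %*% t(G)
  P <- (P + t(P)) / 2
  list(x = x, P = P, dx = dx, jitter = jitter)
}

# ---- full filter ------------------------------------------------------------

#' Correction toggles for the filter
#'
#' @param zupt,tilt,joint_center,joint_axis logical; enable each of the four
#'   measurement models. With all four disabled the filter degenerates to
#'   raw strapdown integration (prediction only).
#' @return a named logical list.
#' @export
correction_config <- function(zupt = TRUE, tilt = TRUE, joint_center = TRUE,
                              joint_axis = TRUE) {
  list(zupt = zupt, tilt = tilt, joint_center = joint_center,
       joint_axis = joint_axis)
}

#' Run the seven-body error-state Kalman filter over an IMU recording
#'
#' Per time step: strapdown prediction of every IMU's position, velocity and
#' orientation with covariance propagation; then a batch measurement update
#' stacking, as available, joint-center events for all six joints (every
#' step), soft-hinge joint-axis events for both knees and both hips (every
#' step; knee and hip noises differ, no ankle axis event), zero-velocity
#' updates at detected footfalls and gravitational tilt events for every IMU
#' inside a detected still interval (suppressed when the accelerometer
#' magnitude is outside `[0.8, 1.2] |g|`). Steps with no events pass the
#' prediction through unchanged.
#'
#' @param imu_data tibble with columns `t`, `imu`, `ax..az`, `gx..gz`; all
#'   seven IMUs on a common uniform time base.
#' @param calibration a [gait_calibration()].
#' @param x0 initial state: named list of per-IMU `p`, `v`, `q` (e.g.
#'   [truth_initial_state()]).
#' @param noise a [noise_config()].
#' @param corrections a [correction_config()].
#' @param still optional precomputed [detect_still()] output; computed from
#'   `imu_data` when omitted.
#' @param footfalls optional precomputed [detect_footfalls()] output.
#' @param still_threshold,still_min_duration,min_stance detection settings
#'   passed to [detect_still()] / [detect_footfalls()].
#' @param P0 initial error covariance; defaults to [initial_covariance()].
#' @return an object of class `erkf_fit`: tibble `poses` (t, imu, position,
#'   velocity, quaternion), event counts, detections and configuration.
#' @export
run_erkf <- function(imu_data, calibration, x0,
                     noise = noise_config(),
                     corrections = correction_config(),
                     still = NULL, footfalls = NULL,
                     still_threshold = 60 * pi / 180,
                     still_min_duration = 0.05, min_stance = 0.1,
                     P0 = NULL) {
  imus <- imu_names()
  if (!setequal(unique(imu_data$imu), imus))
    stop("imu_data must contain exactly the seven IMUs: ",
         paste(imus, collapse = ", "), call. = FALSE)
  streams <- lapply(stats::setNames(imus, imus), function(nm) {
    d <- dplyr::arrange(dplyr::filter(imu_data, .data$imu == nm), .data$t)
    list(t = d$t, a = cbind(d$ax, d$ay, d$az), w = cbind(d$gx, d$gy, d$gz))
  })
  N <- length(streams[[1]]$t)
  for (nm in imus) if (length(streams[[nm]]$t) != N)
    stop("IMU streams have unequal lengths", call. = FALSE)
  tt <- streams[[1]]$t
  dt <- stats::median(diff(tt))

  x <- erkf_state(x0[imus])
  P <- P0 %||% initial_covariance(imus)
  nd <- 9L * length(imus)
  gmag <- sqrt(sum(noise$g^2))

  need_detect <- corrections$zupt || corrections$tilt
  if (need_detect && is.null(still))
    still <- detect_still(imu_data, threshold = still_threshold,
                          min_duration = still_min_duration)
  if (corrections$zupt && is.null(footfalls))
    footfalls <- detect_footfalls(still, imu_data, min_stance = min_stance)

  still_mask <- matrix(FALSE, N, length(imus),
                       dimnames = list(NULL, imus))
  if (corrections$tilt && !is.null(still)) {
    for (i in seq_len(nrow(still))) {
      still_mask[still$start_index[i]:(still$end_index[i] - 1L),
                 still$imu[i]] <- TRUE
    }
  }
  ff_mask <- matrix(FALSE, N, 2, dimnames = list(NULL, foot_imus()))
  if (corrections$zupt && !is.null(footfalls) && nrow(footfalls) > 0) {
    for (i in seq_len(nrow(footfalls)))
      ff_mask[footfalls$index[i], footfalls$foot[i]] <- TRUE
  }

  # static event descriptors (state-independent parts)
  jc_events <- list(); ja_events <- list()
  if (corrections$joint_center) {
    jc_events <- lapply(calibration$joints, function(j)
      make_joint_center(j$proximal, j$distal, j$r_prox, j$r_dist, noise))
  }
  if (corrections$joint_axis) {
    for (jn in names(calibration$joints)) {
      if (grepl("^ankle", jn)) next
      j <- calibration$joints[[jn]]
      sig <- if (grepl("^knee", jn)) noise$sigma_ja_knee else noise$sigma_ja_hip
      ja_events[[jn]] <- make_joint_axis(j$proximal, j$distal,
                                         j$e_prox, j$e_dist, sig)
    }
  }

  qdiag <- process_noise_diag(length(imus), noise, dt)
  OUT <- matrix(NA_real_, N, 10L * length(imus))
  for (j in seq_along(imus))
    OUT[1, 10L * (j - 1L) + 1:10] <- c(x$p[j, ], x$v[j, ], x$q[j, ])
  counts <- c(ZUPT = 0L, TILT = 0L, JOINT_CENTER = 0L, JOINT_AXIS = 0L,
              suppressed_tilt = 0L, jitter = 0L)
  a_step <- matrix(0, length(imus), 3)
  w_step <- matrix(0, length(imus), 3)

  for (k in seq_len(N - 1L)) {
    for (j in seq_along(imus)) {
      a_step[j, ] <- streams[[j]]$a[k, ]
      w_step[j, ] <- streams[[j]]$w[k, ]
    }
    u <- list(a = a_step, w = w_step)
    Fx <- process_jacobian(x, u, dt)
    x <- predict_state(x, u, dt, noise)
    if (any(!is.finite(x$p)) || any(!is.finite(x$q)))
      stop("non-finite state at step ", k + 1,
           "; last good state stored at step ", k, call. = FALSE)
    P <- Fx %*% P %*% t(Fx)
    diag(P) <- diag(P) + qdiag
    P <- (P + t(P)) / 2

    events <- c(jc_events, ja_events)
    kk <- k + 1L
    if (corrections$zupt) {
      for (f in foot_imus()) if (ff_mask[kk, f]) {
        events[[length(events) + 1L]] <- make_zupt(f, noise)
        counts["ZUPT"] <- counts["ZUPT"] + 1L
      }
    }
    if (corrections$tilt) {
      for (j in seq_along(imus)) if (still_mask[kk, j]) {
        ev <- make_tilt(imus[j], streams[[j]]$a[kk, ], noise)
        if (is.null(ev)) {
          counts["suppressed_tilt"] <- counts["suppressed_tilt"] + 1L
        } else {
          events[[length(events) + 1L]] <- ev
          counts["TILT"] <- counts["TILT"] + 1L
        }
      }
    }
    if (length(events) > 0) {
      up <- batch_update(x, P, events)
      x <- up$x; P <- up$P
      if (up$jitter) counts["jitter"] <- counts["jitter"] + 1L
      counts["JOINT_CENTER"] <- counts["JOINT_CENTER"] + length(jc_events)
      counts["JOINT_AXIS"] <- counts["JOINT_AXIS"] + length(ja_events)
    }
    for (j in seq_along(imus))
      OUT[kk, 10L * (j - 1L) + 1:10] <- c(x$p[j, ], x$v[j, ], x$q[j, ])
  }

  poses <- dplyr::bind_rows(lapply(seq_along(imus), function(j) {
    m <- OUT[, 10L * (j - 1L) + 1:10, drop = FALSE]
    tibble::tibble(t = tt, imu = imus[j],
                   px = m[, 1], py = m[, 2], pz = m[, 3],
                   vx = m[, 4], vy = m[, 5], vz = m[, 6],
                   qw = m[, 7], qx = m[, 8], qy = m[, 9], qz = m[, 10])
  }))
  structure(list(poses = poses, P = P, counts = counts,
                 still = still, footfalls = footfalls,
                 noise = noise, corrections = corrections,
                 calibration = calibration, fs = 1 / dt, n_steps = N),
            class = "erkf_fit")
}

#' @export
print.erkf_fit <- function(x, ...) {
  cat("<erkf_fit>", x$n_steps, "steps @", round(x$fs, 3), "Hz | events:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}
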
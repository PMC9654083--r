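#' Specify a synthetic treadmill gait
#'
#' Builds the parameter set for the seven-segment gait generator. Six gait
#' types are supported: forward walking at three speeds, backward walking and
#' lateral walking in both directions. Belt speed and stride length defaults
#' follow typical self-selected treadmill values for each gait type; the
#' stride rate is their ratio, so ground-truth stride length equals
#' `belt_speed / stride_rate` by construction.
#'
#' The world frame is x forward (facing direction), y left, z up; gravity
#' acts along -z. The subject always faces +x; the progression direction
#' depends on the gait type (+x forward, -x backward, +/-y lateral).
#'
#' @param gait_type one of `"forward_slow"`, `"forward_normal"`,
#'   `"forward_fast"`, `"backward"`, `"lateral_left"`, `"lateral_right"`.
#' @param belt_speed treadmill belt speed, m/s (default per gait type).
#' @param stride_length mean stride length, m (default per gait type); the
#'   stride period is `stride_length / belt_speed`.
#' @param duration trial duration, s.
#' @param fs IMU sampling rate, Hz.
#' @param stance_dwell_fraction fraction of the stride period during which
#'   each foot is exactly still.
#' @param step_width lateral separation of the two feet's stride lines, m
#'   (default per gait type; ~0 for lateral gaits).
#' @param swing_clearance peak foot lift during swing, m.
#' @param swing_pitch_deg peak foot pitch during swing, degrees.
#' @param swing_yaw_deg peak foot yaw wobble during swing, degrees. The pitch
#'   and yaw bumps have offset stationary points and act over a fixed
#'   ~0.55 s mid-swing window, so the foot gyroscope magnitude clearly
#'   exceeds the 60 deg/s still-detection threshold throughout the rotation
#'   window at every gait speed — one contiguous still interval per stance.
#' @param pelvis list of pelvis oscillation amplitudes: `bob` (m, vertical at
#'   step frequency), `sway` (m, lateral at stride frequency), `surge` (m,
#'   fore-aft at step frequency), `yaw`, `list`, `pitch` (deg, at stride /
#'   stride / step frequency).
#' @param anthropometry list: `thigh`, `shank` (m), `hip_height` (mid-hip
#'   height, m), `hip_halfwidth` (m), `ankle_height` (m).
#' @param seed integer seed recorded in the spec (used by
#'   [synthesize_imu()] when noise is added).
#' @return an object of class `gait_spec`.
#' @export
gait_spec <- function(gait_type = c("forward_normal", "forward_slow",
                                    "forward_fast", "backward",
                                    "lateral_left", "lateral_right"),
                      belt_speed = NULL, stride_length = NULL,
                      duration = 60, fs = 128,
                      stance_dwell_fraction = 0.35,
                      step_width = NULL,
                      swing_clearance = 0.05,
                      swing_pitch_deg = 22,
                      swing_yaw_deg = 25,
                      pelvis = list(),
                      anthropometry = list(),
                      seed = 1L) {
  gait_type <- match.arg(gait_type)
  defaults <- list(
    forward_slow   = list(belt = 0.47, sl = 0.84, sw = 0.12),
    forward_normal = list(belt = 0.86, sl = 1.09, sw = 0.12),
    forward_fast   = list(belt = 1.32, sl = 1.40, sw = 0.12),
    backward       = list(belt = 0.43, sl = 0.62, sw = 0.15),
    lateral_left   = list(belt = 0.39, sl = 0.48, sw = 0.01),
    lateral_right  = list(belt = 0.38, sl = 0.46, sw = 0.01)
  )[[gait_type]]
  belt_speed <- belt_speed %||% defaults$belt
  stride_length <- stride_length %||% defaults$sl
  step_width <- step_width %||% defaults$sw
  if (belt_speed <= 0) stop("belt_speed must be > 0", call. = FALSE)
  if (stance_dwell_fraction <= 0 || stance_dwell_fraction >= 1)
    stop("stance_dwell_fraction must be in (0, 1)", call. = FALSE)
  stride_rate <- belt_speed / stride_length
  if (stride_rate * duration < 4)
    stop("trial too short: fewer than 4 strides", call. = FALSE)
  pelvis <- utils::modifyList(list(bob = 0.015, sway = 0.025, surge = 0.02,
                                   yaw = 5, list = 3, pitch = 2), pelvis)
  anthropometry <- utils::modifyList(
    list(thigh = 0.44, shank = 0.43, hip_height = 0.84,
         hip_halfwidth = 0.09, ankle_height = 0.09), anthropometry)
  structure(list(gait_type = gait_type, belt_speed = belt_speed,
                 stride_length = stride_length, stride_rate = stride_rate,
                 duration = duration, fs = fs,
                 stance_dwell_fraction = stance_dwell_fraction,
                 step_width = step_width,
                 swing_clearance = swing_clearance,
                 swing_pitch_deg = swing_pitch_deg,
                 swing_yaw_deg = swing_yaw_deg,
                 pelvis = pelvis, anthropometry = anthropometry,
                 seed = as.integer(seed)),
            class = "gait_spec")
}

#' @export
print.gait_spec <- function(x, ...) {
  cat("<gait_spec>", x$gait_type, "| belt", x$belt_speed, "m/s | stride",
      x$stride_length, "m |", x$duration, "s @", x$fs, "Hz\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# upright anatomical-to-world rotation: anatomical X (anterior) -> world x,
# Y (superior) -> world z, Z (subject right) -> world -y
.R_upright <- matrix(c(1, 0, 0,
                       0, 0, -1,
                       0, 1, 0), 3, 3, byrow = TRUE)

rows_norm <- function(M) sqrt(rowSums(M^2))
rows_unit <- function(M) M / rows_norm(M)
rows_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}
rows_dot <- function(A, B) rowSums(A * B)

# quaternion rows for rotation about a fixed world axis by angle theta (vector)
qrows_axis_angle <- function(axis, theta) {
  cbind(cos(theta / 2), outer(sin(theta / 2), axis))
}

# quintic smoothstep and its derivative (zero value/slope/curvature at ends)
smoothstep5 <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
smoothstep5_d <- function(u) 30 * u^2 * (1 - u)^2
# C2 bump, zero with two vanishing derivatives at both ends, max 1 at u = 1/2
bump3 <- function(u) 64 * u^3 * (1 - u)^3
bump3_d <- function(u) 192 * u^2 * (1 - u)^2 * (1 - 2 * u)

# trapezoid-consistent cumulative integral: returns p with
# p[k+1] = p[k] + (v[k] + v[k+1]) * dt / 2 exactly
cumtrapz_rows <- function(v, dt, p0) {
  n <- nrow(v)
  inc <- (v[-n, , drop = FALSE] + v[-1, , drop = FALSE]) * dt / 2
  p <- apply(inc, 2, cumsum)
  rbind(p0, sweep(p, 2, p0, `+`))
}

# exact inverse of cumtrapz_rows: v[k+1] = 2 (p[k+1]-p[k])/dt - v[k],
# solved in closed (cumsum) form via the substitution w_k = (-1)^k v_k
trapz_velocity_rows <- function(p, dt, v0) {
  n <- nrow(p)
  b <- 2 * (p[-1, , drop = FALSE] - p[-n, , drop = FALSE]) / dt
  sgn <- rep_len(c(-1, 1), n - 1) # (-1)^(j+1) for j = 0, 1, ...
  w <- rbind(v0, sweep(apply(b * sgn, 2, cumsum), 2, v0, `+`))
  w * rep_len(c(1, -1), n)
}

# vectorised Shepperd conversion: N x 9 row-major rotation rows -> N x 4 quats
qrows_from_matrix_rows <- function(M) {
  r11 <- M[, 1]; r12 <- M[, 2]; r13 <- M[, 3]
  r21 <- M[, 4]; r22 <- M[, 5]; r23 <- M[, 6]
  r31 <- M[, 7]; r32 <- M[, 8]; r33 <- M[, 9]
  t0 <- 1 + r11 + r22 + r33
  t1 <- 1 + r11 - r22 - r33
  t2 <- 1 - r11 + r22 - r33
  t3 <- 1 - r11 - r22 + r33
  pick <- max.col(cbind(t0, t1, t2, t3), ties.method = "first")
  q <- matrix(0, nrow(M), 4)
  i <- pick == 1
  if (any(i)) {
    s <- 2 * sqrt(t0[i])
    q[i, ] <- cbind(s / 4, (r32[i] - r23[i]) / s, (r13[i] - r31[i]) / s,
                    (r21[i] - r12[i]) / s)
  }
  i <- pick == 2
  if (any(i)) {
    s <- 2 * sqrt(t1[i])
    q[i, ] <- cbind((r32[i] - r23[i]) / s, s / 4, (r12[i] + r21[i]) / s,
                    (r13[i] + r31[i]) / s)
  }
  i <- pick == 3
  if (any(i)) {
    s <- 2 * sqrt(t2[i])
    q[i, ] <- cbind((r13[i] - r31[i]) / s, (r12[i] + r21[i]) / s, s / 4,
                    (r23[i] + r32[i]) / s)
  }
  i <- pick == 4
  if (any(i)) {
    s <- 2 * sqrt(t3[i])
    q[i, ] <- cbind((r21[i] - r12[i]) / s, (r13[i] + r31[i]) / s,
                    (r23[i] + r32[i]) / s, s / 4)
  }
  qrows_normalize(q)
}

# asymmetric C2 bump for the foot yaw wobble: peak 1 at u = 5/8, zero value /
# slope / curvature at both ends; its stationary point is offset from the
# pitch bump's (u = 1/2) so the two-axis angular rate never vanishes inside
# the rotation window
bump53 <- function(u) u^5 * (1 - u)^3 / (0.625^5 * 0.375^3)
bump53_d <- function(u) (5 * u^4 * (1 - u)^3 - 3 * u^5 * (1 - u)^2) /
  (0.625^5 * 0.375^3)

# analytic foot root: ankle trajectory + two-axis foot rotation with exact
# dwell windows. The rotation is confined to a fixed-duration window in
# mid-swing so that the gyroscope magnitude clearly exceeds the still
# threshold there regardless of gait speed, while the foot is rotationally
# quiet through dwell and the swing edges (one contiguous still interval per
# stance).
.foot_root <- function(tt, T_str, phase, dwell_frac, dir, lat, sl,
                       clearance, pitch_amp, yaw_amp, ankle_h,
                       rot_window_max = 0.55) {
  D <- dwell_frac * T_str
  S <- T_str - D
  Srot <- min(0.8 * S, rot_window_max)
  wfrac <- Srot / S
  c0 <- (1 - wfrac) / 2
  i <- floor(tt / T_str - phase + 0.5)
  tau <- tt - (i + phase) * T_str
  # fold early-swing samples onto the previous stride
  early <- tau < -D / 2
  i[early] <- i[early] - 1
  tau[early] <- tau[early] + T_str
  in_swing <- tau > D / 2
  u <- ifelse(in_swing, (tau - D / 2) / S, 0)
  s <- smoothstep5(u); sd <- smoothstep5_d(u) / S
  b <- bump3(u); bd <- bump3_d(u) / S
  ur <- pmin(1, pmax(0, (u - c0) / wfrac))
  along <- (i + phase + s) * sl
  p <- cbind(0, 0, ankle_h + clearance * b) +
    outer(along, dir) + matrix(lat, length(tt), 3, byrow = TRUE)
  v <- outer(sd * sl, dir) + cbind(0, 0, clearance * bd)
  v[!in_swing, ] <- 0
  theta <- pitch_amp * bump3(ur)
  theta_d <- pitch_amp * bump3_d(ur) / Srot
  phi <- yaw_amp * bump53(ur)
  phi_d <- yaw_amp * bump53_d(ur) / Srot
  theta[!in_swing] <- 0; theta_d[!in_swing] <- 0
  phi[!in_swing] <- 0; phi_d[!in_swing] <- 0
  list(p = p, v = v, theta = theta, theta_d = theta_d,
       phi = phi, phi_d = phi_d, stride = i, in_swing = in_swing)
}

.default_mountings <- function() {
  # IMU origin in the segment anatomical frame (m) and a fixed, deliberately
  # non-trivial anatomical-to-sensor rotation per segment
  list(
    pelvis  = list(o = c(-0.10, 0.05, 0.00), R_as = rodrigues(c(0.15, -0.10, 0.30))),
    thigh_l = list(o = c(0.02, -0.20, -0.06), R_as = rodrigues(c(-0.20, 0.40, 0.10))),
    thigh_r = list(o = c(0.02, -0.20, 0.06), R_as = rodrigues(c(0.25, -0.30, -0.15))),
    shank_l = list(o = c(0.01, -0.15, -0.05), R_as = rodrigues(c(0.35, 0.10, -0.20))),
    shank_r = list(o = c(0.01, -0.15, 0.05), R_as = rodrigues(c(-0.15, -0.25, 0.20))),
    foot_l  = list(o = c(0.06, -0.03, -0.01), R_as = rodrigues(c(0.10, 0.20, -0.30))),
    foot_r  = list(o = c(0.06, -0.03, 0.01), R_as = rodrigues(c(-0.25, 0.15, 0.10)))
  )
}

# joint center / heel locations in each segment's anatomical frame
.segment_points <- function(anthro) {
  list(
    hip_in_pelvis = function(side) c(0, 0, ifelse(side == "r", 1, -1) * anthro$hip_halfwidth),
    knee_in_thigh = c(0, -anthro$thigh, 0),
    ankle_in_shank = c(0, -anthro$shank, 0),
    heel_in_foot = c(-0.05, -0.07, 0)
  )
}

#' Generate kinematically consistent seven-segment gait ground truth
#'
#' Produces per-IMU pose streams (position, velocity, orientation), joint
#' angle streams, footfall times, still dwell windows, heel trajectories and
#' the exact sensor-to-segment calibration used — everything needed to
#' synthesise IMU data and score estimates against truth.
#'
#' Construction guarantees three invariants that make the output a strict
#' oracle for the filter:
#' * position and velocity streams satisfy the discrete strapdown relation
#'   `p[k+1] = p[k] + (v[k] + v[k+1]) dt / 2` exactly, so noise-free
#'   synthesised IMU data integrates back to truth at machine precision;
#' * both feet are exactly still (velocity identically zero, constant
#'   orientation) inside every stance dwell window;
#' * the six joint-center coincidence residuals vanish at every sample (the
#'   leg segments are placed by exact two-link inverse kinematics between
#'   the pelvis and foot roots, with the knee acting as an exact hinge).
#'
#' @param spec a [gait_spec()].
#' @return an object of class `gait_truth` with tibbles `imu` (per-IMU pose
#'   stream), `angles` (joint angles, degrees), `footfalls`, `dwell`,
#'   `heel`, plus the `gait_calibration` used and the input `spec`.
#' @export
simulate_gait <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  fs <- spec$fs; dt <- 1 / fs
  tt <- seq(0, spec$duration, by = dt)
  n <- length(tt)
  an <- spec$anthropometry
  T_str <- 1 / spec$stride_rate
  f_str <- spec$stride_rate; f_step <- 2 * f_str
  mount <- .default_mountings()
  pts <- .segment_points(an)
  deg <- pi / 180

  dir <- switch(spec$gait_type,
                forward_slow = , forward_normal = , forward_fast = c(1, 0, 0),
                backward = c(-1, 0, 0),
                lateral_left = c(0, 1, 0),
                lateral_right = c(0, -1, 0))
  lateral_gait <- spec$gait_type %in% c("lateral_left", "lateral_right")
  # stride-line offsets of the two ankles, perpendicular to progression
  if (lateral_gait) {
    lat_l <- c(spec$step_width / 2, 0, 0)
    lat_r <- c(-spec$step_width / 2, 0, 0)
  } else {
    lat_l <- c(0, spec$step_width / 2, 0)
    lat_r <- c(0, -spec$step_width / 2, 0)
  }

  # ---- analytic roots: two feet -------------------------------------------
  feet <- list(
    foot_l = .foot_root(tt, T_str, 0, spec$stance_dwell_fraction, dir, lat_l,
                        spec$stride_length, spec$swing_clearance,
                        spec$swing_pitch_deg * deg, spec$swing_yaw_deg * deg,
                        an$ankle_height),
    foot_r = .foot_root(tt, T_str, 0.5, spec$stance_dwell_fraction, dir, lat_r,
                        spec$stride_length, spec$swing_clearance,
                        spec$swing_pitch_deg * deg, spec$swing_yaw_deg * deg,
                        an$ankle_height)
  )

  q_up <- matrix_to_quat(.R_upright)
  streams <- list() # per IMU: p, v, q
  q_wa <- list()    # per segment: anatomical orientation stream (N x 4)

  for (f in names(feet)) {
    fr <- feet[[f]]
    # foot swing rotation: yaw about world z composed with pitch about world
    # y (medial-lateral when facing +x); angular velocity is
    # phi_d * zhat + theta_d * Rz(phi) yhat
    q_rot <- qrows_multiply(qrows_axis_angle(c(0, 0, 1), fr$phi),
                            qrows_axis_angle(c(0, 1, 0), fr$theta))
    q_wa[[f]] <- qrows_continuous(qrows_multiply(
      q_rot, matrix(q_up, n, 4, byrow = TRUE)))
    o_w0 <- drop(.R_upright %*% mount[[f]]$o)
    o_w <- qrows_rotate(q_rot, matrix(o_w0, n, 3, byrow = TRUE))
    p_an <- fr$p + o_w
    omega_f <- cbind(-fr$theta_d * sin(fr$phi),
                     fr$theta_d * cos(fr$phi),
                     fr$phi_d)
    v_an <- fr$v + rows_cross(omega_f, o_w)
    q_as <- matrix_to_quat(mount[[f]]$R_as)
    q_ws <- qrows_multiply(q_wa[[f]],
                           matrix(quat_conjugate(q_as), n, 4, byrow = TRUE))
    p_k <- cumtrapz_rows(v_an, dt, p_an[1, ])
    streams[[f]] <- list(p = p_k, v = v_an, q = qrows_continuous(q_ws))
  }

  # ---- analytic root: pelvis ----------------------------------------------
  pv <- spec$pelvis
  ph <- c(yaw = 0, pitch = pi / 3, roll = pi / 2, bob = pi / 4,
          sway = pi / 2, surge = 0) # fixed phase offsets
  yaw <- pv$yaw * deg * sin(2 * pi * f_str * tt + ph["yaw"])
  pit <- pv$pitch * deg * sin(2 * pi * f_step * tt + ph["pitch"])
  rol <- pv$list * deg * sin(2 * pi * f_str * tt + ph["roll"])
  yaw_d <- pv$yaw * deg * 2 * pi * f_str * cos(2 * pi * f_str * tt + ph["yaw"])
  pit_d <- pv$pitch * deg * 2 * pi * f_step * cos(2 * pi * f_step * tt + ph["pitch"])
  rol_d <- pv$list * deg * 2 * pi * f_str * cos(2 * pi * f_str * tt + ph["roll"])
  # mid-hip point: mean progression plus bob / sway / surge oscillations
  perp <- if (lateral_gait) c(1, 0, 0) else c(0, 1, 0)
  B <- outer(spec$belt_speed * tt, dir) +
    outer(pv$sway * sin(2 * pi * f_str * tt + ph["sway"]), perp) +
    outer(pv$surge * sin(2 * pi * f_step * tt + ph["surge"]), dir) +
    cbind(0, 0, an$hip_height + pv$bob * sin(2 * pi * f_step * tt + ph["bob"]))
  B_d <- outer(spec$belt_speed + pv$surge * 2 * pi * f_step *
                 cos(2 * pi * f_step * tt + ph["surge"]), dir) +
    outer(pv$sway * 2 * pi * f_str * cos(2 * pi * f_str * tt + ph["sway"]), perp) +
    cbind(0, 0, pv$bob * 2 * pi * f_step * cos(2 * pi * f_step * tt + ph["bob"]))
  q_wa$pelvis <- qrows_continuous(qrows_multiply(
    qrows_multiply(qrows_axis_angle(c(0, 0, 1), yaw),
                   qrows_multiply(qrows_axis_angle(c(0, 1, 0), pit),
                                  qrows_axis_angle(c(1, 0, 0), rol))),
    matrix(q_up, n, 4, byrow = TRUE)))
  # angular velocity of Rz(yaw) Ry(pit) Rx(rol): yaw_d z + Rz (pit_d y) + Rz Ry (rol_d x)
  omega_p <- cbind(-pit_d * sin(yaw) + rol_d * cos(yaw) * cos(pit),
                   pit_d * cos(yaw) + rol_d * sin(yaw) * cos(pit),
                   yaw_d - rol_d * sin(pit))
  o_pw <- qrows_rotate(q_wa$pelvis, matrix(mount$pelvis$o, n, 3, byrow = TRUE))
  p_an <- B + o_pw
  v_an <- B_d + rows_cross(omega_p, o_pw)
  q_as_p <- matrix_to_quat(mount$pelvis$R_as)
  q_ws_p <- qrows_continuous(qrows_multiply(
    q_wa$pelvis, matrix(quat_conjugate(q_as_p), n, 4, byrow = TRUE)))
  streams$pelvis <- list(p = cumtrapz_rows(v_an, dt, p_an[1, ]),
                         v = v_an, q = q_ws_p)

  # ---- close the leg loops by exact two-link inverse kinematics ----------
  bend <- qrows_rotate(q_wa$pelvis, matrix(c(1, 0, 0), n, 3, byrow = TRUE))
  for (side in c("l", "r")) {
    foot <- paste0("foot_", side)
    thigh <- paste0("thigh_", side)
    shank <- paste0("shank_", side)
    r_hip_imu <- drop(mount$pelvis$R_as %*%
                        (pts$hip_in_pelvis(side) - mount$pelvis$o))
    Hc <- streams$pelvis$p +
      qrows_rotate(streams$pelvis$q, matrix(r_hip_imu, n, 3, byrow = TRUE))
    r_ankle_imu <- drop(mount[[foot]]$R_as %*% (0 - mount[[foot]]$o))
    Ac <- streams[[foot]]$p +
      qrows_rotate(streams[[foot]]$q, matrix(r_ankle_imu, n, 3, byrow = TRUE))
    w <- Ac - Hc
    D <- rows_norm(w)
    Lmax <- 0.999 * (an$thigh + an$shank)
    if (any(D > Lmax)) {
      warning("hip-ankle distance clamped on ", sum(D > Lmax), " samples (",
              side, " leg); consider shorter strides or longer legs")
      fac <- pmin(1, Lmax / D)
      Ac <- Hc + w * fac
      w <- Ac - Hc
      D <- rows_norm(w)
    }
    what <- w / D
    u0 <- bend - what * rows_dot(bend, what)
    uhat <- rows_unit(u0)
    tstar <- (an$thigh^2 - an$shank^2 + D^2) / (2 * D)
    cperp <- sqrt(pmax(an$thigh^2 - tstar^2, 1e-12))
    K <- Hc + what * tstar + uhat * cperp
    Yt <- (Hc - K) / an$thigh
    Zt <- rows_unit(rows_cross(Hc - K, Ac - K))
    Xt <- rows_cross(Yt, Zt)
    Ys <- (K - Ac) / an$shank
    Xs <- rows_cross(Ys, Zt)
    q_wa[[thigh]] <- qrows_continuous(qrows_from_matrix_rows(
      cbind(Xt[, 1], Yt[, 1], Zt[, 1], Xt[, 2], Yt[, 2], Zt[, 2],
            Xt[, 3], Yt[, 3], Zt[, 3])))
    q_wa[[shank]] <- qrows_continuous(qrows_from_matrix_rows(
      cbind(Xs[, 1], Ys[, 1], Zt[, 1], Xs[, 2], Ys[, 2], Zt[, 2],
            Xs[, 3], Ys[, 3], Zt[, 3])))
    for (seg in c(thigh, shank)) {
      q_as <- matrix_to_quat(mount[[seg]]$R_as)
      q_ws <- qrows_continuous(qrows_multiply(
        q_wa[[seg]], matrix(quat_conjugate(q_as), n, 4, byrow = TRUE)))
      # anatomical origin is the proximal joint center (hip for the thigh,
      # knee for the shank), so the anchor offset is -o in the sensor frame
      anchor <- if (seg == thigh) Hc else K
      r_anchor <- drop(mount[[seg]]$R_as %*% (0 - mount[[seg]]$o))
      p_k <- anchor - qrows_rotate(q_ws, matrix(r_anchor, n, 3, byrow = TRUE))
      v0 <- (-3 * p_k[1, ] + 4 * p_k[2, ] - p_k[3, ]) / (2 * dt)
      streams[[seg]] <- list(p = p_k,
                             v = trapz_velocity_rows(p_k, dt, v0),
                             q = q_ws)
    }
  }

  # ---- calibration --------------------------------------------------------
  cal_imus <- lapply(stats::setNames(imu_names(), imu_names()), function(nm)
    list(segment = nm, R_as = mount[[nm]]$R_as))
  z_axis <- c(0, 0, 1)
  mk_joint <- function(prox, dist, p_prox_anat, p_dist_anat, hinge) {
    j <- list(proximal = prox, distal = dist,
              r_prox = drop(mount[[prox]]$R_as %*% (p_prox_anat - mount[[prox]]$o)),
              r_dist = drop(mount[[dist]]$R_as %*% (p_dist_anat - mount[[dist]]$o)))
    if (hinge) {
      j$e_prox <- drop(mount[[prox]]$R_as %*% z_axis)
      j$e_dist <- drop(mount[[dist]]$R_as %*% z_axis)
    }
    j
  }
  cal_joints <- list(
    hip_l = mk_joint("pelvis", "thigh_l", pts$hip_in_pelvis("l"), c(0, 0, 0), TRUE),
    hip_r = mk_joint("pelvis", "thigh_r", pts$hip_in_pelvis("r"), c(0, 0, 0), TRUE),
    knee_l = mk_joint("thigh_l", "shank_l", pts$knee_in_thigh, c(0, 0, 0), TRUE),
    knee_r = mk_joint("thigh_r", "shank_r", pts$knee_in_thigh, c(0, 0, 0), TRUE),
    ankle_l = mk_joint("shank_l", "foot_l", pts$ankle_in_shank, c(0, 0, 0), FALSE),
    ankle_r = mk_joint("shank_r", "foot_r", pts$ankle_in_shank, c(0, 0, 0), FALSE)
  )
  cal_heel <- list(
    foot_l = drop(mount$foot_l$R_as %*% (pts$heel_in_foot - mount$foot_l$o)),
    foot_r = drop(mount$foot_r$R_as %*% (pts$heel_in_foot - mount$foot_r$o))
  )
  calibration <- gait_calibration(cal_imus, cal_joints, cal_heel)

  # ---- truth joint angles -------------------------------------------------
  ang <- list()
  for (jn in joint_names()) {
    j <- cal_joints[[jn]]
    side <- substr(jn, nchar(jn), nchar(jn))
    q_rel <- qrows_multiply(qrows_conjugate(q_wa[[j$proximal]]),
                            q_wa[[j$distal]])
    a3 <- qrows_zxy_angles(q_rel, side)
    ang[[jn]] <- tibble::tibble(
      t = tt, joint = sub("_[lr]$", "", jn), side = side,
      fe = a3[, 1], abad = a3[, 2], ie = a3[, 3])
  }
  angles <- dplyr::bind_rows(ang)

  # ---- footfalls, dwell windows, heel paths -------------------------------
  ff <- list(); dw <- list(); heel <- list()
  for (side in c("l", "r")) {
    f <- paste0("foot_", side)
    phase <- if (side == "l") 0 else 0.5
    Dd <- spec$stance_dwell_fraction * T_str
    centers <- (seq(-2, ceiling(spec$duration / T_str) + 2) + phase) * T_str
    centers <- centers[centers >= 0 & centers <= spec$duration]
    idx <- round(centers * fs) + 1
    keep <- idx >= 1 & idx <= n
    ff[[side]] <- tibble::tibble(foot = f, t = tt[idx[keep]],
                                 index = idx[keep])
    st <- pmax(centers - Dd / 2, 0); en <- pmin(centers + Dd / 2, spec$duration)
    dw[[side]] <- tibble::tibble(foot = f, t_start = st, t_end = en,
                                 start_index = round(st * fs) + 1,
                                 end_index = round(en * fs) + 1)
    hp <- streams[[f]]$p +
      qrows_rotate(streams[[f]]$q, matrix(cal_heel[[f]], n, 3, byrow = TRUE))
    heel[[side]] <- tibble::tibble(t = tt, foot = f, x = hp[, 1],
                                   y = hp[, 2], z = hp[, 3])
  }

  imu_tbl <- dplyr::bind_rows(lapply(imu_names(), function(nm) {
    s <- streams[[nm]]
    tibble::tibble(t = tt, imu = nm,
                   px = s$p[, 1], py = s$p[, 2], pz = s$p[, 3],
                   vx = s$v[, 1], vy = s$v[, 2], vz = s$v[, 3],
                   qw = s$q[, 1], qx = s$q[, 2], qy = s$q[, 3], qz = s$q[, 4])
  }))

  structure(list(spec = spec, calibration = calibration,
                 imu = imu_tbl, angles = angles,
                 footfalls = dplyr::bind_rows(ff),
                 dwell = dplyr::bind_rows(dw),
                 heel = dplyr::bind_rows(heel),
                 t = tt, fs = fs,
                 streams = streams),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat("<gait_truth>", x$spec$gait_type, "|", length(x$t), "samples @",
      x$fs, "Hz |", nrow(x$footfalls), "footfalls\n")
  invisible(x)
}

#' Initial filter state from simulator truth
#'
#' @param truth a `gait_truth`.
#' @return a named list of per-IMU poses (`p`, `v`, `q`) at the first sample,
#'   suitable as `x0` for [run_erkf()].
#' @export
truth_initial_state <- function(truth) {
  lapply(truth$streams, function(s)
    list(p = s$p[1, ], v = s$v[1, ], q = s$q[1, ]))
}

#' Synthesise IMU accelerometer and gyroscope streams from ground truth
#'
#' Inverts the strapdown process model exactly at the recorded sample times:
#' the specific force is `a[k] = R[k]^T ((v[k+1] - v[k]) / dt - g)` (a
#' stationary level IMU reads `+9.81` on its z axis) and the angular rate is
#' the discrete quaternion log `omega[k] = (2/dt) log(q[k]* (x) q[k+1])`.
#' Because truth positions satisfy the trapezoid relation, integrating the
#' noise-free output with [predict_state()] reproduces the truth poses to
#' machine precision. Optional additive white Gaussian noise and constant
#' gyro bias model IMU-grade sensing.
#'
#' @param truth a `gait_truth`.
#' @param noise a [noise_config()] supplying `sigma_a` and `sigma_omega`, or
#'   `NULL` for noise-free output.
#' @param seed RNG seed for the noise draw; defaults to the spec's seed.
#' @param gyro_bias length-3 constant gyro bias (rad/s) added to every IMU,
#'   default zero.
#' @param soft_tissue optional list emulating soft-tissue artefact: a small
#'   sinusoidal rotation of the sensor relative to its segment, applied to
#'   the thigh IMUs (fields `amplitude_deg`, `freq_hz`, optionally `imus`).
#'   The artefact perturbs the *measured* signals only; the stored ground
#'   truth (and the calibration the filter uses) keep the nominal constant
#'   mounting, so the filter sees a time-varying sensor-to-segment
#'   alignment it does not model. Default off.
#' @return tibble with columns `t`, `imu`, `ax ay az` (m/s^2), `gx gy gz`
#'   (rad/s).
#' @export
synthesize_imu <- function(truth, noise = NULL, seed = NULL,
                           gyro_bias = c(0, 0, 0), soft_tissue = NULL) {
  stopifnot(inherits(truth, "gait_truth"))
  dt <- 1 / truth$fs
  g <- if (is.null(noise)) c(0, 0, -9.81) else noise$g
  if (!is.null(soft_tissue)) {
    soft_tissue <- utils::modifyList(
      list(amplitude_deg = 2, freq_hz = 1, imus = c("thigh_l", "thigh_r")),
      soft_tissue)
  }
  out <- lapply(imu_names(), function(nm) {
    s <- truth$streams[[nm]]
    n <- nrow(s$p)
    if (!is.null(soft_tissue) && nm %in% soft_tissue$imus) {
      wob <- soft_tissue$amplitude_deg * pi / 180 *
        sin(2 * pi * soft_tissue$freq_hz * truth$t)
      s$q <- qrows_multiply(s$q, qrows_axis_angle(c(1, 0, 0), wob))
    }
    dv <- (s$v[-1, , drop = FALSE] - s$v[-n, , drop = FALSE]) / dt
    fw <- sweep(dv, 2, g) # world specific force
    a <- qrows_rotate(qrows_conjugate(s$q[-n, , drop = FALSE]), fw)
    a <- rbind(a, a[n - 1, ])
    dq <- qrows_multiply(qrows_conjugate(s$q[-n, , drop = FALSE]),
                         s$q[-1, , drop = FALSE])
    w <- qrows_to_rotvec(dq) / dt
    w <- rbind(w, w[n - 1, ])
    tibble::tibble(t = truth$t, imu = nm,
                   ax = a[, 1], ay = a[, 2], az = a[, 3],
                   gx = w[, 1] + gyro_bias[1], gy = w[, 2] + gyro_bias[2],
                   gz = w[, 3] + gyro_bias[3])
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(noise)) {
    set.seed(seed %||% truth$spec$seed)
    m <- nrow(out)
    out$ax <- out$ax + stats::rnorm(m, 0, noise$sigma_a)
    out$ay <- out$ay + stats::rnorm(m, 0, noise$sigma_a)
    out$az <- out$az + stats::rnorm(m, 0, noise$sigma_a)
    out$gx <- out$gx + stats::rnorm(m, 0, noise$sigma_omega)
    out$gy <- out$gy + stats::rnorm(m, 0, noise$sigma_omega)
    out$gz <- out$gz + stats::rnorm(m, 0, noise$sigma_omega)
  }
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits per-IMU CSV streams, the calibration YAML, ground-truth pose /
#' angle / footfall CSVs and a manifest recording the spec and its hash, so
#' a fixture can be regenerated and verified bit-for-bit.
#'
#' @param spec a [gait_spec()].
#' @param out_dir output directory (created if needed).
#' @param noise optional [noise_config()] for the IMU streams.
#' @return invisibly, the manifest path.
#' @export
emit_fixture <- function(spec, out_dir, noise = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_gait(spec)
  imu <- synthesize_imu(truth, noise = noise)
  write_imu_csv(imu, file.path(out_dir, "imu.csv"))
  write_calibration_yaml(truth$calibration, file.path(out_dir, "calibration.yaml"))
  readr::write_csv(truth$imu, file.path(out_dir, "truth_poses.csv"))
  readr::write_csv(truth$angles, file.path(out_dir, "truth_angles.csv"))
  readr::write_csv(truth$footfalls, file.path(out_dir, "truth_footfalls.csv"))
  spec_plain <- unclass(spec)
  manifest <- list(schema = "imugait-fixture/1",
                   spec = spec_plain,
                   spec_hash = rlang::hash(spec_plain),
                   noisy = !is.null(noise))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"), precision = 15)
  invisible(file.path(out_dir, "manifest.yaml"))
}
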
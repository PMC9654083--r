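#' Segment orientation from IMU orientation and mounting rotation
#'
#' The world-from-anatomical rotation is `R_wa = R_ws %*% R_as`: a vector in
#' anatomical coordinates maps through `R_as` into the sensor frame and
#' through the IMU orientation `R_ws` into the world.
#'
#' @param q_imu unit quaternion of the IMU (body-to-world).
#' @param R_as 3x3 anatomical-to-sensor rotation.
#' @return 3x3 world-from-anatomical rotation.
#' @export
segment_orientation <- function(q_imu, R_as) {
  if (!is_rotation_matrix(R_as))
    stop("R_as is not orthonormal with det +1", call. = FALSE)
  quat_to_matrix(q_imu) %*% R_as
}

# intrinsic Z-X-Y joint-coordinate decomposition, vectorised over quaternion
# rows of the proximal-to-distal relative rotation; returns degrees with the
# left-side AbAd / IE sign mirroring applied
qrows_zxy_angles <- function(Qrel, side) {
  w <- Qrel[, 1]; x <- Qrel[, 2]; y <- Qrel[, 3]; z <- Qrel[, 4]
  m12 <- 2 * (x * y - w * z)
  m22 <- 1 - 2 * (x^2 + z^2)
  m31 <- 2 * (x * z - w * y)
  m32 <- 2 * (y * z + w * x)
  m33 <- 1 - 2 * (x^2 + y^2)
  beta <- asin(pmin(1, pmax(-1, m32)))
  gimbal <- abs(cos(beta)) < 1e-6
  alpha <- atan2(-m12, m22)
  gamma <- atan2(-m31, m33)
  out <- cbind(alpha, beta, gamma) * 180 / pi
  out[gimbal, ] <- NaN
  if (side == "l") out[, 2:3] <- -out[, 2:3]
  out
}

#' Joint angles from adjacent segment orientations
#'
#' Decomposes the relative rotation `t(R_proximal) %*% R_distal` in the
#' body-fixed Z-X-Y joint coordinate sequence: flexion/extension about the
#' proximal medial-lateral (z) axis, internal/external rotation about the
#' distal longitudinal (y) axis, and abduction/adduction about the floating
#' x axis. Left-side AbAd and IE are sign-mirrored so positive means
#' adduction / internal rotation on both sides. For the ankle the same
#' triple reads as dorsiflexion/plantarflexion, inversion/eversion and
#' internal/external rotation.
#'
#' Near gimbal lock (`|cos(abad)| < 1e-6`) the decomposition is undefined
#' and `NaN` is returned with a warning; anatomical joints stay far from
#' this configuration.
#'
#' @param R_proximal,R_distal 3x3 world-from-anatomical rotations.
#' @param side `"l"` or `"r"`.
#' @param joint joint name, recorded in the result names only.
#' @return named numeric `(fe, abad, ie)` in degrees.
#' @export
joint_angles <- function(R_proximal, R_distal, side = c("r", "l"),
                         joint = "joint") {
  side <- match.arg(side)
  if (!is_rotation_matrix(R_proximal) || !is_rotation_matrix(R_distal))
    stop("inputs must be orthonormal rotations", call. = FALSE)
  q <- matrix_to_quat(t(R_proximal) %*% R_distal)
  a <- qrows_zxy_angles(matrix(q, 1, 4), side)
  if (any(is.nan(a))) warning("gimbal proximity in ", joint, "; returning NaN")
  stats::setNames(as.numeric(a), c("fe", "abad", "ie"))
}

#' Compose a Z-X-Y joint rotation from its angle triple
#'
#' Inverse of [joint_angles()] (right-side sign semantics): builds
#' `Rz(fe) %*% Rx(abad) %*% Ry(ie)`.
#'
#' @param fe,abad,ie angles in degrees.
#' @param side `"l"` or `"r"`; for `"l"` the AbAd/IE mirroring is undone
#'   before composing.
#' @return 3x3 relative rotation (proximal to distal).
#' @export
joint_angle_matrix <- function(fe, abad, ie, side = "r") {
  if (side == "l") {
    abad <- -abad; ie <- -ie
  }
  d <- pi / 180
  rodrigues(c(0, 0, fe * d)) %*% rodrigues(c(abad * d, 0, 0)) %*%
    rodrigues(c(0, ie * d, 0))
}

#' Zero-lag low-pass Butterworth filtering
#'
#' Fourth-order Butterworth applied forward and backward (zero phase). The
#' design cutoff is pre-warped by `(sqrt(2)-1)^(-1/(2*order))` so the
#' two-pass -3 dB point sits at `fc`. The series is reflection-padded
#' before the bidirectional pass to suppress end transients. `NA` gaps
#' split the series into segments filtered independently; segments shorter
#' than `min_segment` are set to `NA` (skipped), since the filter cannot
#' warm up on them.
#'
#' @param series numeric vector (may contain `NA` gaps).
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz; must exceed `2 * fc`.
#' @param order filter order (of each pass).
#' @param min_segment minimum filterable segment length, seconds.
#' @return filtered series, same length.
#' @export
lowpass_zero_lag <- function(series, fc = 6, fs = 128, order = 4,
                             min_segment = 0.2) {
  if (fs <= 2 * fc) stop("fs must exceed 2 * fc", call. = FALSE)
  fc_design <- fc * (sqrt(2) - 1)^(-1 / (2 * order))
  bf <- signal::butter(order, 2 * fc_design / fs, type = "low")
  out <- rep(NA_real_, length(series))
  ok <- is.finite(series)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  min_len <- max(as.integer(round(min_segment * fs)), 3L * (order + 1L))
  skipped <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    seg <- series[starts[i]:ends[i]]
    n <- length(seg)
    if (n < min_len) {
      skipped <- skipped + 1L
      next
    }
    pad <- min(n - 1L, as.integer(round(fs)))
    # odd reflection padding at both ends
    head_pad <- 2 * seg[1] - seg[(pad + 1):2]
    tail_pad <- 2 * seg[n] - seg[(n - 1):(n - pad)]
    f <- signal::filtfilt(bf, c(head_pad, seg, tail_pad))
    out[starts[i]:ends[i]] <- f[(pad + 1):(pad + n)]
  }
  if (skipped > 0)
    message(skipped, " segment(s) shorter than ", min_segment,
            " s skipped by the zero-lag filter")
  out
}

#' Joint angles from an estimated (or true) pose stream
#'
#' Maps each IMU's orientation stream through its anatomical-to-sensor
#' rotation, forms each joint's proximal-to-distal relative rotation and
#' decomposes it into the Z-X-Y angle triple. Angle series are optionally
#' low-pass filtered with the zero-lag Butterworth filter.
#'
#' @param poses an `erkf_fit`, a `gait_truth`, or a tibble with columns
#'   `t`, `imu`, `qw..qz`.
#' @param calibration a [gait_calibration()].
#' @param lowpass apply [lowpass_zero_lag()] to each angle series.
#' @param fc,fs filter settings; `fs` defaults to the stream rate.
#' @return tibble with columns `t`, `joint` (`hip`/`knee`/`ankle`), `side`,
#'   `fe`, `abad`, `ie` (degrees). For the ankle, `fe` is
#'   dorsi/plantarflexion and `abad` inversion/eversion.
#' @export
estimate_joint_angles <- function(poses, calibration, lowpass = TRUE,
                                  fc = 6, fs = NULL) {
  if (inherits(poses, "erkf_fit")) poses <- poses$poses
  if (inherits(poses, "gait_truth")) poses <- poses$imu
  qs <- list()
  for (nm in unique(poses$imu)) {
    d <- dplyr::arrange(dplyr::filter(poses, .data$imu == nm), .data$t)
    q_as <- matrix_to_quat(calibration$imus[[nm]]$R_as)
    qs[[nm]] <- qrows_multiply(cbind(d$qw, d$qx, d$qy, d$qz),
                               matrix(q_as, nrow(d), 4, byrow = TRUE))
    tt <- d$t
  }
  fs <- fs %||% 1 / stats::median(diff(tt))
  out <- lapply(names(calibration$joints), function(jn) {
    j <- calibration$joints[[jn]]
    side <- substr(jn, nchar(jn), nchar(jn))
    q_rel <- qrows_multiply(qrows_conjugate(qs[[j$proximal]]), qs[[j$distal]])
    a <- qrows_zxy_angles(q_rel, side)
    if (lowpass) a <- apply(a, 2, lowpass_zero_lag, fc = fc, fs = fs)
    tibble::tibble(t = tt, joint = sub("_[lr]$", "", jn), side = side,
                   fe = a[, 1], abad = a[, 2], ie = a[, 3])
  })
  dplyr::bind_rows(out)
}

#' Heel trajectory from a foot IMU pose stream
#'
#' `p_heel(t) = p_imu(t) + R_imu(t) %*% heel_offset`.
#'
#' @param poses an `erkf_fit`, `gait_truth`, or pose tibble (columns `t`,
#'   `imu`, `px..pz`, `qw..qz`).
#' @param calibration a [gait_calibration()] supplying per-foot heel
#'   offsets in the foot IMU frame.
#' @return tibble `t`, `foot`, `x`, `y`, `z` (m).
#' @export
heel_trajectory <- function(poses, calibration) {
  if (inherits(poses, "erkf_fit")) poses <- poses$poses
  if (inherits(poses, "gait_truth")) poses <- poses$imu
  out <- lapply(names(calibration$heel), function(f) {
    d <- dplyr::arrange(dplyr::filter(poses, .data$imu == f), .data$t)
    hp <- cbind(d$px, d$py, d$pz) +
      qrows_rotate(cbind(d$qw, d$qx, d$qy, d$qz),
                   matrix(calibration$heel[[f]], nrow(d), 3, byrow = TRUE))
    tibble::tibble(t = d$t, foot = f, x = hp[, 1], y = hp[, 2], z = hp[, 3])
  })
  dplyr::bind_rows(out)
}

#' Per-stride range of motion
#'
#' A stride spans successive same-side footfalls; for every joint angle of
#' that side the range of motion is the within-stride maximum minus
#' minimum. A stride is invalid (ROM `NA`) if any sample of the angle
#' series inside it is missing.
#'
#' @param angles tibble from [estimate_joint_angles()].
#' @param footfalls tibble from [detect_footfalls()] (or simulator truth).
#' @return tibble `foot`, `stride`, `t_start`, `t_end`, `joint`, `angle`,
#'   `rom` (degrees), `valid`.
#' @export
range_of_motion <- function(angles, footfalls) {
  out <- list()
  for (side in c("l", "r")) {
    f <- paste0("foot_", side)
    ft <- sort(footfalls$t[footfalls$foot == f])
    if (length(ft) < 2) next
    asd <- dplyr::filter(angles, .data$side == !!side)
    for (s in seq_len(length(ft) - 1)) {
      w <- asd$t >= ft[s] & asd$t <= ft[s + 1]
      for (jn in unique(asd$joint)) {
        d <- asd[w & asd$joint == jn, ]
        for (ang in c("fe", "abad", "ie")) {
          v <- d[[ang]]
          valid <- length(v) > 0 && all(is.finite(v))
          out[[length(out) + 1L]] <- tibble::tibble(
            foot = f, stride = s, t_start = ft[s], t_end = ft[s + 1],
            joint = jn, angle = ang,
            rom = if (valid) max(v) - min(v) else NA_real_,
            valid = valid)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(foot = character(), stride = integer(),
                          t_start = numeric(), t_end = numeric(),
                          joint = character(), angle = character(),
                          rom = numeric(), valid = logical()))
  }
  dplyr::bind_rows(out)
}

#' Trial-level range-of-motion summary
#'
#' Mean and SD of the per-stride ROM for each joint angle. If more than
#' `max_invalid_fraction` of the strides for a joint angle are invalid, no
#' summary is reported for it (`mean`/`sd` set to `NA`, `suppressed` TRUE).
#'
#' @param rom tibble from [range_of_motion()].
#' @param max_invalid_fraction suppression threshold (default 30%).
#' @return tibble `foot`, `joint`, `angle`, `n_strides`, `n_valid`,
#'   `mean`, `sd`, `suppressed`.
#' @export
rom_summary <- function(rom, max_invalid_fraction = 0.3) {
  rom |>
    dplyr::group_by(.data$foot, .data$joint, .data$angle) |>
    dplyr::summarise(
      n_strides = dplyr::n(), n_valid = sum(.data$valid),
      suppressed = mean(!.data$valid) > max_invalid_fraction,
      mean = ifelse(.data$suppressed[1], NA_real_,
                    mean(.data$rom[.data$valid])),
      sd = ifelse(.data$suppressed[1], NA_real_,
                  stats::sd(.data$rom[.data$valid])),
      .groups = "drop")
}

#' Stride length and step width
#'
#' Stride length is the horizontal (world xy) displacement of a foot's heel
#' between consecutive footfalls of that foot. Step width is the
#' perpendicular distance from the opposite foot's heel at the intermediate
#' footfall to the supporting line of the stride vector. The first stride
#' and last two strides of each foot are treadmill transition strides and
#' are dropped by default. A stride with no intermediate opposite-foot
#' footfall gets `sw = NA`.
#'
#' @param heel tibble from [heel_trajectory()] covering both feet.
#' @param footfalls tibble from [detect_footfalls()].
#' @param drop_transition drop the first stride and last two strides per
#'   foot.
#' @return tibble `foot`, `stride`, `t_start`, `t_end`, `sl`, `sw` (m).
#' @export
stride_metrics <- function(heel, footfalls, drop_transition = TRUE) {
  res <- list()
  heel_at <- function(f, idx) {
    d <- dplyr::arrange(dplyr::filter(heel, .data$foot == f), .data$t)
    cbind(d$x[idx], d$y[idx])
  }
  for (f in c("foot_l", "foot_r")) {
    other <- setdiff(c("foot_l", "foot_r"), f)
    ff <- dplyr::arrange(dplyr::filter(footfalls, .data$foot == f), .data$t)
    fo <- dplyr::arrange(dplyr::filter(footfalls, .data$foot == other), .data$t)
    if (nrow(ff) < if (drop_transition) 4L else 2L) {
      if (drop_transition && nrow(ff) >= 2)
        warning("fewer than 4 footfalls for ", f,
                "; no non-transition strides available")
      next
    }
    hp <- heel_at(f, ff$index)
    ho <- heel_at(other, fo$index)
    n_str <- nrow(ff) - 1
    keep <- if (drop_transition) setdiff(seq_len(n_str), c(1, n_str - 1, n_str))
            else seq_len(n_str)
    for (s in keep) {
      a <- hp[s, ]; b <- hp[s + 1, ]
      sl <- sqrt(sum((b - a)^2))
      mid <- which(fo$t > ff$t[s] & fo$t < ff$t[s + 1])
      if (length(mid) == 0) {
        sw <- NA_real_
      } else {
        # the intermediate opposite footfall (closest to mid-stride if several)
        m <- mid[which.min(abs(fo$t[mid] - (ff$t[s] + ff$t[s + 1]) / 2))]
        p <- ho[m, ]
        sw <- if (sl < 1e-12) {
          sqrt(sum((p - a)^2))
        } else {
          abs((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) / sl
        }
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        foot = f, stride = s, t_start = ff$t[s], t_end = ff$t[s + 1],
        sl = sl, sw = sw)
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(foot = character(), stride = integer(),
                          t_start = numeric(), t_end = numeric(),
                          sl = numeric(), sw = numeric()))
  }
  dplyr::bind_rows(res)
}
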
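# centered rolling standard deviation with edge-truncated windows
.rolling_sd <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  s1 <- cs[hi + 1L] - cs[lo]; s2 <- cs2[hi + 1L] - cs2[lo]
  sqrt(pmax(s2 / m - (s1 / m)^2, 0))
}

#' Detect still periods from raw IMU signals
#'
#' A sample is still-candidate when the angular velocity magnitude is below
#' `threshold` and, when accelerometer columns are available, the local
#' variability of the specific-force magnitude (rolling standard deviation
#' over `accel_window`) is below `accel_band` — a genuinely still sensor
#' senses pure gravity reaction, so its accelerometer magnitude is locally
#' constant, whereas a slowly rotating but accelerating segment is not
#' still. Maximal runs of still-candidates at least `min_duration` long are
#' reported as still intervals, per IMU. Only signal norms are used, so
#' detection is invariant to any fixed rotation of the sensor frame.
#'
#' @param imu_data tibble with columns `t`, `imu`, `gx`, `gy`, `gz` (rad/s)
#'   and optionally `ax`, `ay`, `az` (m/s^2), uniformly sampled per IMU (as
#'   produced by [synthesize_imu()] or [read_imu_csv()]).
#' @param threshold still threshold on `|omega|`, rad/s; default 60 deg/s.
#' @param min_duration minimum still duration, seconds.
#' @param accel_band threshold on the rolling standard deviation of `|a|`,
#'   m/s^2; `NULL` disables the accelerometer-stationarity condition.
#' @param accel_window rolling window for the accelerometer condition, s.
#' @return tibble with columns `imu`, `start_index`, `end_index` (half-open,
#'   1-based sample indices into that IMU's stream), `t_start`, `t_end`.
#' @export
detect_still <- function(imu_data, threshold = 60 * pi / 180,
                         min_duration = 0.05,
                         accel_band = 0.08, accel_window = 0.15) {
  if (nrow(imu_data) == 0) {
    return(tibble::tibble(imu = character(), start_index = integer(),
                          end_index = integer(), t_start = numeric(),
                          t_end = numeric()))
  }
  use_accel <- !is.null(accel_band) && all(c("ax", "ay", "az") %in%
                                             names(imu_data))
  imu_data |>
    dplyr::group_by(.data$imu) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$t)
      fs <- 1 / stats::median(diff(d$t))
      min_len <- max(1L, as.integer(round(min_duration * fs)))
      still <- sqrt(d$gx^2 + d$gy^2 + d$gz^2) < threshold
      if (use_accel) {
        anorm <- sqrt(d$ax^2 + d$ay^2 + d$az^2)
        half <- max(1L, as.integer(round(accel_window * fs / 2)))
        still <- still & .rolling_sd(anorm, half) < accel_band
      }
      r <- rle(still)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_len
      tibble::tibble(start_index = starts[keep],
                     end_index = ends[keep] + 1L,
                     t_start = d$t[starts[keep]],
                     t_end = d$t[ends[keep]])
    }) |>
    dplyr::ungroup()
}

#' Identify one footfall instant per stance
#'
#' Within each qualifying still interval of a foot IMU (length at least
#' `min_stance`), the footfall is the sample minimising the stillness score
#' `|omega| + lambda * | |a| - g |` — the instant at which the foot is both
#' rotationally quiet and sensing pure gravity reaction. Ties break to the
#' earliest index. Exactly one footfall is reported per qualifying interval,
#' so re-running detection is idempotent.
#'
#' @param still output of [detect_still()] for the same streams.
#' @param imu_data tibble with `t`, `imu`, `ax..az` (m/s^2), `gx..gz`
#'   (rad/s).
#' @param feet character vector naming the foot IMUs.
#' @param min_stance minimum still-interval duration eligible for a
#'   footfall, seconds.
#' @param lambda weight (seconds) of the specific-force term in the score.
#' @param gravity gravitational magnitude, m/s^2.
#' @return tibble with columns `foot`, `t`, `index` (1-based sample index
#'   into that foot's stream), sorted by time within foot.
#' @export
detect_footfalls <- function(still, imu_data, feet = c("foot_l", "foot_r"),
                             min_stance = 0.1, lambda = 1,
                             gravity = 9.81) {
  out <- list()
  for (f in feet) {
    d <- dplyr::arrange(dplyr::filter(imu_data, .data$imu == f), .data$t)
    iv <- dplyr::filter(still, .data$imu == f,
                        .data$t_end - .data$t_start >= min_stance)
    if (nrow(iv) == 0) next
    score <- sqrt(d$gx^2 + d$gy^2 + d$gz^2) +
      lambda * abs(sqrt(d$ax^2 + d$ay^2 + d$az^2) - gravity)
    idx <- vapply(seq_len(nrow(iv)), function(i) {
      rng <- iv$start_index[i]:(iv$end_index[i] - 1L)
      rng[which.min(score[rng])]
    }, integer(1))
    out[[f]] <- tibble::tibble(foot = f, t = d$t[idx], index = idx)
  }
  if (length(out) == 0) {
    return(tibble::tibble(foot = character(), t = numeric(),
                          index = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$foot, .data$t)
}
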
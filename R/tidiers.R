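#' Tidy an error-state filter fit
#'
#' Returns the estimated pose trajectory as one row per sample per IMU.
#'
#' @param x an `erkf_fit`.
#' @param ... unused.
#' @return tibble `t`, `imu`, `px..pz`, `vx..vz`, `qw..qz`.
#' @export
tidy.erkf_fit <- function(x, ...) x$poses

#' One-row summary of an error-state filter fit
#'
#' @param x an `erkf_fit`.
#' @param ... unused.
#' @return one-row tibble: steps, sampling rate, counts of each applied
#'   measurement kind, suppressed tilt events and regularised innovation
#'   solves.
#' @export
glance.erkf_fit <- function(x, ...) {
  tibble::tibble(n_steps = x$n_steps, fs = x$fs,
                 n_zupt = unname(x$counts["ZUPT"]),
                 n_tilt = unname(x$counts["TILT"]),
                 n_joint_center = unname(x$counts["JOINT_CENTER"]),
                 n_joint_axis = unname(x$counts["JOINT_AXIS"]),
                 n_suppressed_tilt = unname(x$counts["suppressed_tilt"]),
                 n_jitter = unname(x$counts["jitter"]))
}

#' Plot an error-state filter fit
#'
#' Estimated IMU positions (or velocities) over time, faceted by axis.
#'
#' @param object an `erkf_fit`.
#' @param what `"position"` or `"velocity"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.erkf_fit <- function(object, what = c("position", "velocity"), ...) {
  what <- match.arg(what)
  cols <- if (what == "position") c("px", "py", "pz") else c("vx", "vy", "vz")
  d <- tidyr::pivot_longer(object$poses, dplyr::all_of(cols),
                           names_to = "axis", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value,
                                  colour = .data$imu)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = if (what == "position") "position (m)" else "velocity (m/s)")
}

#' Plot joint-angle time series
#'
#' @param angles tibble from [estimate_joint_angles()].
#' @param reference optional second angle table (e.g. simulator truth)
#'   overlaid as a dashed line.
#' @return a ggplot faceted by joint and angle.
#' @export
plot_joint_angles <- function(angles, reference = NULL) {
  longify <- function(d, src) {
    tidyr::pivot_longer(d, dplyr::all_of(c("fe", "abad", "ie")),
                        names_to = "angle", values_to = "deg") |>
      dplyr::mutate(source = src)
  }
  d <- longify(angles, "estimate")
  if (!is.null(reference)) d <- dplyr::bind_rows(d, longify(reference, "reference"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$deg,
                                  colour = .data$side,
                                  linetype = .data$source)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(joint ~ angle, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)")
}

#' Plot per-stride stride length and step width
#'
#' @param strides tibble from [stride_metrics()].
#' @return a ggplot.
#' @export
plot_strides <- function(strides) {
  d <- tidyr::pivot_longer(strides, dplyr::all_of(c("sl", "sw")),
                           names_to = "metric", values_to = "m")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start, y = .data$m,
                                  colour = .data$foot)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "stride start (s)", y = "metres")
}
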
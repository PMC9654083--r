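#' Read and write IMU streams as CSV
#'
#' Long format, one row per sample per IMU: columns `t` (s), `imu`,
#' `ax ay az` (specific force, m/s^2), `gx gy gz` (angular rate, rad/s).
#'
#' @param imu_data tibble in the above format.
#' @param path file path.
#' @return `read_imu_csv` returns the tibble; `write_imu_csv` returns
#'   `path` invisibly.
#' @export
write_imu_csv <- function(imu_data, path) {
  readr::write_csv(imu_data, path)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "imu", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("IMU CSV ", path, " lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !vapply(d[setdiff(need, "imu")], is.numeric, logical(1))
  if (any(bad))
    stop("IMU CSV ", path, " has non-numeric columns: ",
         paste(setdiff(need, "imu")[bad], collapse = ", "), call. = FALSE)
  d
}

#' Read / write a noise configuration as YAML
#'
#' Angular sigmas are stored in deg (and deg/s) as in [noise_config()]'s
#' arguments.
#'
#' @param noise a [noise_config()].
#' @param path file path.
#' @return `read_noise_yaml` returns a `noise_config`;
#'   `write_noise_yaml` returns `path` invisibly.
#' @export
write_noise_yaml <- function(noise, path) {
  yaml::write_yaml(list(
    schema = "imugait-noise/1",
    sigma_a = noise$sigma_a,
    sigma_omega_deg = noise$sigma_omega * 180 / pi,
    sigma_zv = noise$sigma_zv,
    sigma_tilt_deg = noise$sigma_tilt * 180 / pi,
    sigma_jc = noise$sigma_jc,
    sigma_ja_knee_deg = noise$sigma_ja_knee * 180 / pi,
    sigma_ja_hip_deg = noise$sigma_ja_hip * 180 / pi,
    g = as.numeric(noise$g)), path, precision = 15)
  invisible(path)
}

#' @rdname write_noise_yaml
#' @export
read_noise_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "imugait-noise/1"))
    stop("unrecognised noise schema: ", doc$schema, call. = FALSE)
  noise_config(sigma_a = doc$sigma_a, sigma_omega_deg = doc$sigma_omega_deg,
               sigma_zv = doc$sigma_zv, sigma_tilt_deg = doc$sigma_tilt_deg,
               sigma_jc = doc$sigma_jc,
               sigma_ja_knee_deg = doc$sigma_ja_knee_deg,
               sigma_ja_hip_deg = doc$sigma_ja_hip_deg,
               g = as.numeric(doc$g))
}

#' RMS differences between two joint-angle tables
#'
#' Joins by time, joint and side and reports the root-mean-square
#' difference for each angle series, ignoring samples missing in either.
#'
#' @param estimate,reference tibbles from [estimate_joint_angles()].
#' @return tibble `joint`, `side`, `angle`, `rms` (degrees), `n`.
#' @export
angle_rms_error <- function(estimate, reference) {
  j <- dplyr::inner_join(estimate, reference,
                         by = c("t", "joint", "side"),
                         suffix = c("_est", "_ref"))
  out <- lapply(c("fe", "abad", "ie"), function(ang) {
    e <- j[[paste0(ang, "_est")]] - j[[paste0(ang, "_ref")]]
    j |>
      dplyr::mutate(err = e) |>
      dplyr::filter(is.finite(.data$err)) |>
      dplyr::group_by(.data$joint, .data$side) |>
      dplyr::summarise(angle = ang, rms = sqrt(mean(.data$err^2)),
                       n = dplyr::n(), .groups = "drop")
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$joint, .data$side, .data$angle)
}

#' Run the full estimation pipeline on an IMU recording
#'
#' Convenience wrapper: event detection, error-state filtering, joint-angle
#' decomposition, heel trajectories and stride metrics in one call. When
#' simulator truth is supplied, per-angle and stride RMS errors against
#' truth are included in the summary.
#'
#' @param imu_data IMU tibble (or path to an IMU CSV).
#' @param calibration a [gait_calibration()] (or path to a calibration
#'   YAML).
#' @param x0 initial state (named per-IMU list of `p`, `v`, `q`).
#' @param noise a [noise_config()].
#' @param corrections a [correction_config()]; disable all four for a raw
#'   strapdown (prediction-only) run.
#' @param truth optional `gait_truth` for scoring.
#' @param lowpass low-pass filter the angle series (see
#'   [estimate_joint_angles()]).
#' @return an object of class `gait_pipeline`: the `erkf_fit`, `angles`,
#'   `heel`, `footfalls`, `strides`, `rom` tibbles and a `summary` list.
#' @export
run_gait_pipeline <- function(imu_data, calibration, x0,
                              noise = noise_config(),
                              corrections = correction_config(),
                              truth = NULL, lowpass = TRUE) {
  if (is.character(imu_data)) imu_data <- read_imu_csv(imu_data)
  if (is.character(calibration)) calibration <- read_calibration_yaml(calibration)
  fit <- run_erkf(imu_data, calibration, x0, noise = noise,
                  corrections = corrections)
  angles <- estimate_joint_angles(fit, calibration, lowpass = lowpass)
  heel <- heel_trajectory(fit, calibration)
  footfalls <- fit$footfalls %||%
    detect_footfalls(detect_still(imu_data), imu_data)
  strides <- if (nrow(footfalls) >= 8) stride_metrics(heel, footfalls) else
    tibble::tibble()
  rom <- if (nrow(footfalls) >= 4) range_of_motion(angles, footfalls) else
    tibble::tibble()
  summary <- list(
    n_steps = fit$n_steps, fs = fit$fs,
    prediction_only = !any(unlist(fit$corrections)),
    event_counts = as.list(fit$counts),
    n_footfalls = nrow(footfalls), n_strides = nrow(strides)
  )
  if (!is.null(truth)) {
    truth_angles <- estimate_joint_angles(truth, calibration,
                                          lowpass = lowpass)
    summary$angle_rms <- angle_rms_error(angles, truth_angles)
    truth_heel <- heel_trajectory(truth, calibration)
    truth_str <- stride_metrics(truth_heel, footfalls)
    if (nrow(strides) > 0 && nrow(truth_str) > 0) {
      cmp <- dplyr::inner_join(strides, truth_str,
                               by = c("foot", "stride"),
                               suffix = c("_est", "_true"))
      summary$sl_rms <- sqrt(mean((cmp$sl_est - cmp$sl_true)^2))
      summary$sw_rms <- sqrt(mean((cmp$sw_est - cmp$sw_true)^2,
                                  na.rm = TRUE))
    }
  }
  structure(list(fit = fit, angles = angles, heel = heel,
                 footfalls = footfalls, strides = strides, rom = rom,
                 summary = summary, calibration = calibration),
            class = "gait_pipeline")
}

#' @export
print.gait_pipeline <- function(x, ...) {
  cat("<gait_pipeline>", x$summary$n_steps, "steps |",
      x$summary$n_footfalls, "footfalls |", x$summary$n_strides, "strides\n")
  if (!is.null(x$summary$angle_rms)) {
    cat("  max angle RMS error:",
        round(max(x$summary$angle_rms$rms), 3), "deg\n")
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Joint angles, strides and ROM as CSV (degrees and metres), the run
#' summary as JSON.
#'
#' @param pipeline a `gait_pipeline`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(pipeline$angles, file.path(out_dir, "angles.csv"))
  if (nrow(pipeline$strides) > 0)
    readr::write_csv(pipeline$strides, file.path(out_dir, "strides.csv"))
  if (nrow(pipeline$rom) > 0)
    readr::write_csv(pipeline$rom, file.path(out_dir, "rom.csv"))
  s <- pipeline$summary
  if (!is.null(s$angle_rms)) s$angle_rms <- as.data.frame(s$angle_rms)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
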
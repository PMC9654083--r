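#' Sensor-to-segment calibration
#'
#' A `gait_calibration` object carries everything the filter and the
#' kinematics layer need to relate IMU sense frames to the underlying
#' skeleton:
#'
#' * per segment, the anatomical-to-sensor rotation `R_as` (maps coordinates
#'   expressed in the segment's anatomical frame to the IMU sense frame, so
#'   the world-from-anatomical rotation is `R_ws %*% R_as`);
#' * per joint, the joint-center offset in each adjacent IMU frame (`r_prox`,
#'   `r_dist`, metres) and, for knees and hips, the flexion/extension axis
#'   unit vector in each adjacent IMU frame (`e_prox`, `e_dist`);
#' * per foot, the heel offset in the foot IMU frame (metres).
#'
#' The seven IMUs are named `pelvis`, `thigh_l`, `thigh_r`, `shank_l`,
#' `shank_r`, `foot_l`, `foot_r`; the six joints `hip_l`, `hip_r`, `knee_l`,
#' `knee_r`, `ankle_l`, `ankle_r`.
#'
#' @param imus named list; each element has fields `segment` and `R_as`.
#' @param joints named list; each element has `proximal`, `distal` (IMU
#'   names), `r_prox`, `r_dist` and optionally `e_prox`, `e_dist`.
#' @param heel named list of length-3 heel offsets for `foot_l`, `foot_r`.
#' @return an object of class `gait_calibration`.
#' @export
gait_calibration <- function(imus, joints, heel) {
  cal <- structure(list(imus = imus, joints = joints, heel = heel),
                   class = "gait_calibration")
  rep <- validate_calibration(cal)
  if (!all(rep$pass)) {
    bad <- rep$check[!rep$pass]
    stop("invalid calibration: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  cal
}

#' @export
print.gait_calibration <- function(x, ...) {
  cat("<gait_calibration>", length(x$imus), "IMUs,", length(x$joints),
      "joints,", length(x$heel), "heel offsets\n")
  invisible(x)
}

imu_names <- function() c("pelvis", "thigh_l", "thigh_r", "shank_l",
                          "shank_r", "foot_l", "foot_r")
joint_names <- function() c("hip_l", "hip_r", "knee_l", "knee_r",
                            "ankle_l", "ankle_r")
foot_imus <- function() c("foot_l", "foot_r")

#' Compose the anatomical-to-sensor rotation from its two factors
#'
#' Combines the cluster-to-sensor rotation with the anatomical-to-cluster
#' rotation, `R_as = R_cs %*% R_ac`, re-orthonormalising through the polar
#' decomposition if floating-point drift has accumulated.
#'
#' @param R_cs,R_ac 3x3 rotation matrices.
#' @return 3x3 rotation matrix `R_as`.
#' @export
compose_ras <- function(R_cs, R_ac) {
  if (!is_rotation_matrix(R_cs)) stop("R_cs is not a rotation matrix", call. = FALSE)
  if (!is_rotation_matrix(R_ac)) stop("R_ac is not a rotation matrix", call. = FALSE)
  orthonormalize_rotation(R_cs %*% R_ac)
}

#' Project a near-rotation matrix onto SO(3)
#'
#' Polar decomposition via SVD with the determinant constrained to +1.
#'
#' @param M 3x3 matrix close to a rotation.
#' @return the nearest (Frobenius) rotation matrix.
#' @export
orthonormalize_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Fit the fixed rotation between two angular-velocity streams
#'
#' Solves the orthogonal Procrustes problem
#' `argmin_R sum_k || omega_ref[k,] - R omega_sens[k,] ||^2` over proper
#' rotations, via SVD of the cross-covariance. This is how the cluster-to-
#' sensor rotation is recovered by comparing raw gyroscope data against the
#' angular velocity of an optically tracked marker cluster during a
#' calibration movement.
#'
#' @param omega_sensor,omega_reference N x 3 matrices (or data frames with
#'   three numeric columns), time-aligned, N >= 3, angular velocities with
#'   non-collinear directions.
#' @return 3x3 rotation `R` with `omega_reference ~ omega_sensor %*% t(R)`.
#' @export
fit_rotation_by_angular_velocity <- function(omega_sensor, omega_reference) {
  ws <- as.matrix(omega_sensor)
  wr <- as.matrix(omega_reference)
  if (!all(dim(ws) == dim(wr)) || ncol(ws) != 3 || nrow(ws) < 3)
    stop("streams must be time-aligned N x 3 with N >= 3", call. = FALSE)
  .check_finite(ws, "sensor stream"); .check_finite(wr, "reference stream")
  M <- crossprod(wr, ws) # sum over k of wr_k ws_k^T
  s <- svd(M)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300))
    stop("under-determined: angular velocities are collinear", call. = FALSE)
  R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  R
}

#' Validate a calibration set
#'
#' Checks the structural invariants (rotations orthonormal with det +1, axis
#' vectors unit-norm, offsets finite and below 1 m) and, when a static pose
#' is supplied, cross-checks that the two axis vectors of each knee/hip map
#' to approximately equal world vectors and that joint-center residuals
#' vanish in that pose.
#'
#' @param cal a `gait_calibration` (or plain list with the same fields).
#' @param static_pose optional named list of per-IMU poses, each with fields
#'   `p` (length-3) and `q` (unit quaternion), e.g. one time slice of
#'   simulator truth.
#' @param axis_tol_deg tolerance for the static axis-consistency check at
#'   hinge-like joints (knees).
#' @param hip_axis_tol_deg tolerance at the hips, which are only softly
#'   hinge-like: their flexion axes need only roughly agree in a static
#'   pose.
#' @param center_tol_m tolerance for the static joint-center residual.
#' @return a tibble with columns `check`, `pass`, `detail`.
#' @export
validate_calibration <- function(cal, static_pose = NULL,
                                 axis_tol_deg = 5, hip_axis_tol_deg = 45,
                                 center_tol_m = 0.01) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)
  }
  add("imu set", setequal(names(cal$imus), imu_names()),
      paste(names(cal$imus), collapse = ","))
  add("joint set", setequal(names(cal$joints), joint_names()),
      paste(names(cal$joints), collapse = ","))
  for (nm in names(cal$imus)) {
    add(paste0("R_as orthonormal: ", nm),
        is_rotation_matrix(cal$imus[[nm]]$R_as))
  }
  for (nm in names(cal$joints)) {
    j <- cal$joints[[nm]]
    ok_r <- all(is.finite(c(j$r_prox, j$r_dist))) &&
      sqrt(sum(j$r_prox^2)) < 1 && sqrt(sum(j$r_dist^2)) < 1
    add(paste0("offsets finite, < 1 m: ", nm), ok_r)
    if (!is.null(j$e_prox)) {
      ok_e <- abs(sqrt(sum(j$e_prox^2)) - 1) < 1e-6 &&
        abs(sqrt(sum(j$e_dist^2)) - 1) < 1e-6
      add(paste0("axes unit-norm: ", nm), ok_e)
    }
  }
  for (nm in names(cal$heel)) {
    add(paste0("heel offset finite, < 1 m: ", nm),
        all(is.finite(cal$heel[[nm]])) && sqrt(sum(cal$heel[[nm]]^2)) < 1)
  }
  if (!is.null(static_pose)) {
    for (nm in names(cal$joints)) {
      j <- cal$joints[[nm]]
      pp <- static_pose[[j$proximal]]; pd <- static_pose[[j$distal]]
      Rp <- quat_to_matrix(pp$q); Rd <- quat_to_matrix(pd$q)
      res <- (pp$p + drop(Rp %*% j$r_prox)) - (pd$p + drop(Rd %*% j$r_dist))
      add(paste0("static joint-center residual: ", nm),
          sqrt(sum(res^2)) < center_tol_m,
          sprintf("%.4f m", sqrt(sum(res^2))))
      if (!is.null(j$e_prox)) {
        wp <- drop(Rp %*% j$e_prox); wd <- drop(Rd %*% j$e_dist)
        ang <- acos(min(1, max(-1, sum(wp * wd)))) * 180 / pi
        tol <- if (grepl("^hip", nm)) hip_axis_tol_deg else axis_tol_deg
        add(paste0("static axis consistency: ", nm), ang < tol,
            sprintf("%.2f deg", ang))
      }
    }
  }
  dplyr::bind_rows(checks)
}

#' Read / write calibration YAML
#'
#' The YAML schema (version 1) stores per-IMU `R_as` as a row-major
#' length-9 vector, per-joint offsets and axes as length-3 vectors, and heel
#' offsets per foot IMU.
#'
#' @param cal a `gait_calibration`.
#' @param path file path.
#' @return `read_calibration_yaml` returns a `gait_calibration`;
#'   `write_calibration_yaml` returns `path` invisibly.
#' @export
write_calibration_yaml <- function(cal, path) {
  doc <- list(
    schema = "imugait-calibration/1",
    imus = lapply(cal$imus, function(s)
      list(segment = s$segment, R_as = as.numeric(t(s$R_as)))),
    joints = lapply(cal$joints, function(j) {
      out <- list(proximal = j$proximal, distal = j$distal,
                  r_prox = as.numeric(j$r_prox), r_dist = as.numeric(j$r_dist))
      if (!is.null(j$e_prox)) {
        out$e_prox <- as.numeric(j$e_prox)
        out$e_dist <- as.numeric(j$e_dist)
      }
      out
    }),
    heel = lapply(cal$heel, as.numeric)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration_yaml
#' @export
read_calibration_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "imugait-calibration/1"))
    stop("unrecognised calibration schema: ", doc$schema, call. = FALSE)
  imus <- lapply(doc$imus, function(s)
    list(segment = s$segment,
         R_as = matrix(as.numeric(s$R_as), 3, 3, byrow = TRUE)))
  joints <- lapply(doc$joints, function(j) {
    out <- list(proximal = j$proximal, distal = j$distal,
                r_prox = as.numeric(j$r_prox), r_dist = as.numeric(j$r_dist))
    if (!is.null(j$e_prox)) {
      out$e_prox <- as.numeric(j$e_prox)
      out$e_dist <- as.numeric(j$e_dist)
    }
    out
  })
  gait_calibration(imus = imus, joints = joints,
                   heel = lapply(doc$heel, as.numeric))
}
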
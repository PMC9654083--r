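#' Quaternion and rotation primitives
#'
#' Hamiltonian unit quaternions stored as length-4 numeric vectors in
#' `(w, x, y, z)` order. A quaternion `q` rotates sensor-frame (body) vectors
#' into the world frame: `y_w = q (x) [0, y_b] (x) q*`. Every function that
#' returns a quaternion renormalises it, so unit norm holds to 1e-9 after any
#' chain of operations. Signs are not canonicalised (both `q` and `-q` encode
#' the same rotation); canonicalisation to `w >= 0` happens only at I/O
#' boundaries to avoid discontinuities inside the filter.
#'
#' @name so3
#' @keywords internal
NULL

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}

#' Normalise a quaternion to unit length
#' @param q numeric length-4, `(w, x, y, z)`.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  .check_finite(q, "quaternion")
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalise a zero quaternion", call. = FALSE)
  q / n
}

#' Hamiltonian quaternion product
#'
#' Computes `a (x) b`, i.e. the rotation that applies `b` first and `a`
#' second when acting on vectors.
#'
#' @param a,b unit quaternions `(w, x, y, z)`.
#' @return the renormalised product quaternion.
#' @export
quat_multiply <- function(a, b) {
  .check_finite(a, "quaternion a")
  .check_finite(b, "quaternion b")
  quat_normalize(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ))
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q unit quaternion.
#' @return `q*`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotate a body-frame vector into the world frame
#'
#' Returns the vector part of `q (x) [0, v] (x) q*`; norm-preserving.
#'
#' @param q unit quaternion (body-to-world).
#' @param v numeric length-3 body-frame vector.
#' @return length-3 world-frame vector.
#' @export
quat_rotate <- function(q, v) {
  .check_finite(q, "quaternion")
  .check_finite(v, "vector")
  # v + 2 w (u x v) + 2 u x (u x v), u = vector part
  u <- q[2:4]
  t2 <- 2 * c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
  v + q[1] * t2 + c(u[2] * t2[3] - u[3] * t2[2],
                    u[3] * t2[1] - u[1] * t2[3],
                    u[1] * t2[2] - u[2] * t2[1])
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion (body-to-world).
#' @return 3x3 rotation matrix `R` with `y_w = R y_b`.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest of the four candidate
#' pivots. The returned sign has `w >= 0`.
#'
#' @param R 3x3 rotation matrix.
#' @return unit quaternion `(w, x, y, z)`.
#' @export
matrix_to_quat <- function(R) {
  .check_finite(R, "rotation matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    s <- sqrt(1 + tr) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Exponential map: rotation vector to unit quaternion
#'
#' `[cos(|v|/2), sin(|v|/2) v/|v|]`; the zero vector maps to the identity by
#' the analytic small-angle limit (no division by zero).
#'
#' @param v numeric length-3 rotation vector (axis times angle, radians).
#' @return unit quaternion.
#' @export
rotvec_to_quat <- function(v) {
  .check_finite(v, "rotation vector")
  phi <- sqrt(sum(v^2))
  if (phi < 1e-12) {
    # second-order series keeps the map smooth through zero
    quat_normalize(c(1 - phi^2 / 8, v / 2))
  } else {
    quat_normalize(c(cos(phi / 2), sin(phi / 2) * v / phi))
  }
}

#' Logarithm map: unit quaternion to rotation vector
#'
#' Inverse of [rotvec_to_quat()]; result canonicalised to magnitude in
#' `[0, pi]`.
#'
#' @param q unit quaternion.
#' @return length-3 rotation vector, radians.
#' @export
quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  sn <- sqrt(sum(q[2:4]^2))
  if (sn < 1e-12) {
    2 * q[2:4] # atan2(sn, w)/sn -> 1/w -> 1 as sn -> 0, w -> 1
  } else {
    2 * atan2(sn, q[1]) * q[2:4] / sn
  }
}

#' Skew-symmetric (cross-product) matrix
#'
#' `skew(y) %*% u == cross(y, u)`.
#'
#' @param y numeric length-3.
#' @return 3x3 skew-symmetric matrix.
#' @export
skew <- function(y) {
  .check_finite(y, "vector")
  matrix(c(0, -y[3], y[2],
           y[3], 0, -y[1],
           -y[2], y[1], 0), nrow = 3, byrow = TRUE)
}

#' Rodrigues rotation matrix of a rotation vector
#'
#' `I cos(phi) + sin(phi) [s]_x + s s^T (1 - cos(phi))` with `w = phi s`;
#' `phi = 0` returns the identity without dividing by zero.
#'
#' @param w numeric length-3 rotation vector, radians.
#' @return 3x3 rotation matrix.
#' @export
rodrigues <- function(w) {
  .check_finite(w, "rotation vector")
  phi <- sqrt(sum(w^2))
  if (phi < 1e-12) {
    diag(3) + skew(w) # first-order; exact at w = 0
  } else {
    s <- w / phi
    diag(3) * cos(phi) + sin(phi) * skew(s) + tcrossprod(s) * (1 - cos(phi))
  }
}

# ---- vectorised internals (row-wise over time) ------------------------------
# Quaternion streams are N x 4 matrices, vector streams N x 3. These are used
# by the simulator and kinematics layers where per-sample loops would dominate.

qrows_normalize <- function(Q) Q / sqrt(rowSums(Q^2))

qrows_multiply <- function(A, B) {
  qrows_normalize(cbind(
    A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
    A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
    A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
    A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  ))
}

qrows_conjugate <- function(Q) cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])

qrows_rotate <- function(Q, V) {
  w <- Q[, 1]; u <- Q[, 2:4, drop = FALSE]
  t2 <- 2 * cbind(u[, 2] * V[, 3] - u[, 3] * V[, 2],
                  u[, 3] * V[, 1] - u[, 1] * V[, 3],
                  u[, 1] * V[, 2] - u[, 2] * V[, 1])
  V + w * t2 + cbind(u[, 2] * t2[, 3] - u[, 3] * t2[, 2],
                     u[, 3] * t2[, 1] - u[, 1] * t2[, 3],
                     u[, 1] * t2[, 2] - u[, 2] * t2[, 1])
}

qrows_to_rotvec <- function(Q) {
  flip <- Q[, 1] < 0
  Q[flip, ] <- -Q[flip, ]
  sn <- sqrt(rowSums(Q[, 2:4, drop = FALSE]^2))
  fac <- ifelse(sn < 1e-12, 2, 2 * atan2(sn, Q[, 1]) / pmax(sn, 1e-300))
  Q[, 2:4, drop = FALSE] * fac
}

# enforce sign continuity along a quaternion stream (rows)
qrows_continuous <- function(Q) {
  s <- cumprod(c(1, ifelse(rowSums(Q[-1, , drop = FALSE] *
                                     Q[-nrow(Q), , drop = FALSE]) < 0, -1, 1)))
  Q * s
}

#' Validity check for rotation matrices
#' @param R 3x3 matrix.
#' @param tol Frobenius tolerance on `R^T R - I`.
#' @return logical.
#' @export
is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == 3) && all(is.finite(R)) &&
    norm(crossprod(R) - diag(3), "F") < tol && det(R) > 0
}
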
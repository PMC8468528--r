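## Rotation-matrix utilities used by the frame-calibration module.

#' Convert a rotation matrix to its rotation vector
#'
#' Maps a 3x3 rotation matrix to the rotation vector (unit axis scaled by the
#' rotation angle) via the matrix logarithm. The angle branch is fixed to
#' `[0, pi)`; rotations within `1e-6` rad of pi are rejected because the axis
#' sign is ambiguous there and element-wise averaging of rotation vectors is
#' only meaningful on a consistent branch.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param tol tolerance on `|det(R) - 1|` and orthonormality.
#' @return numeric length-3 rotation vector (radians).
#' @export
rotation_to_vector <- function(R, tol = 1e-6) {
  check_rotation(R, tol = tol)
  # clamp for safety against rounding just outside [-1, 1]
  ct <- (sum(diag(R)) - 1) / 2
  theta <- acos(min(1, max(-1, ct)))
  if (theta >= pi - 1e-6) {
    stop("rotation angle within 1e-6 of pi: axis sign is ambiguous")
  }
  if (theta < 1e-12) {
    return(c(0, 0, 0))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Convert a rotation vector to a rotation matrix
#'
#' Exponential map: builds the rotation matrix for a rotation of
#' `norm(v)` radians about the axis `v / norm(v)` (Rodrigues' formula).
#'
#' @param v numeric length-3 rotation vector (radians).
#' @return 3x3 rotation matrix.
#' @export
vector_to_rotation <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3, all(is.finite(v)))
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) {
    return(diag(3))
  }
  k <- v / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Geodesic distance between two rotations
#'
#' Angle (radians) of the relative rotation `t(R1) %*% R2`.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_distance <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, ct)))
}

#' Project a near-rotation matrix onto SO(3)
#'
#' Polar projection via SVD; absorbs floating-point drift so downstream code
#' always sees an exactly orthonormal matrix with determinant +1.
#'
#' @param M 3x3 matrix close to a rotation.
#' @return nearest 3x3 rotation matrix (Frobenius norm).
#' @export
project_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  R
}

# error unless R is orthonormal with det +1 within tol
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R))) {
    stop("rotation must be a finite 3x3 matrix")
  }
  if (abs(det(R) - 1) > tol) {
    stop(sprintf("|det - 1| = %.3g exceeds tolerance %.3g", abs(det(R) - 1), tol))
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("matrix is not orthonormal within tolerance")
  }
  invisible(R)
}

# uniformly random unit axis, small rotation of given angle (radians)
random_small_rotation <- function(angle_rad) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  vector_to_rotation(ax * angle_rad)
}
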
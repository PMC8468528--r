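## Frame calibration: estimate the definitive load-cell-to-shank rotation and
## joint-to-sensor offsets from calibration samples, and re-express wrench
## streams in the shank frame.

#' Average rotation matrices by rotation-vector averaging
#'
#' Each sample rotation is converted to its rotation vector (unit axis times
#' angle), the vectors are averaged element-wise, and the mean vector is
#' mapped back through the exponential map. The result is re-projected onto
#' SO(3) to absorb floating-point drift. This is the standard way to pool a
#' few hundred noisy sensor-to-segment orientation samples into one definitive
#' mounting rotation.
#'
#' Samples whose rotation angle is within `1e-6` rad of pi are rejected: at pi
#' the axis sign is ambiguous and element-wise vector averaging breaks down.
#' Mounting orientations in practice are far from a half-turn.
#'
#' @param samples list of 3x3 rotation matrices, or a 3 x 3 x n array.
#' @param tol orthonormality/determinant tolerance for each sample.
#' @return single 3x3 rotation matrix.
#' @export
average_rotation <- function(samples, tol = 1e-6) {
  samples <- as_rotation_list(samples)
  if (length(samples) < 1) stop("need at least one rotation sample")
  vecs <- vapply(samples, rotation_to_vector, numeric(3), tol = tol)
  project_rotation(vector_to_rotation(rowMeans(vecs)))
}

#' Average offset-vector samples
#'
#' Element-wise arithmetic mean of repeated measurements of a joint-to-sensor
#' offset vector.
#'
#' @param samples n x 3 matrix (one row per sample) or list of length-3 vectors.
#' @return numeric length-3 mean vector.
#' @export
average_offset <- function(samples) {
  if (is.list(samples)) {
    samples <- do.call(rbind, samples)
  }
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("need at least one offset sample")
  if (ncol(samples) != 3) stop("offset samples must have 3 components")
  colMeans(samples)
}

#' Rotate a wrench series into the shank frame
#'
#' Applies the calibrated load-cell-to-shank rotation to every force and
#' moment sample. Timestamps are unchanged; the frame tag is updated. Calling
#' this on a series already in the shank frame is an error (double-rotation
#' guard).
#'
#' @param series a `wrench_series` with frame `"load_cell"`.
#' @param geometry a `subject_geometry` holding `rotation_lc_to_shank`.
#' @return a `wrench_series` in the shank frame.
#' @export
to_shank_frame <- function(series, geometry) {
  stopifnot(inherits(series, "wrench_series"), inherits(geometry, "subject_geometry"))
  if (series$frame != "load_cell") {
    stop("series is already in the shank frame (double-rotation guard)")
  }
  R <- geometry$rotation_lc_to_shank
  wrench_series(
    time = series$time,
    force = series$force %*% t(R),
    moment = series$moment %*% t(R),
    frame = "shank"
  )
}

#' Calibrate subject geometry from paired orientation/offset samples
#'
#' Convenience wrapper combining [average_rotation()] and [average_offset()]
#' into a `subject_geometry`.
#'
#' @param rotations list or 3 x 3 x n array of rotation samples.
#' @param ankle_offsets,knee_offsets n x 3 matrices of offset samples, m.
#' @param foot_length foot length, m.
#' @param body_weight body weight, N.
#' @return a `subject_geometry` with averaged rotation and offsets.
#' @export
calibrate_geometry <- function(rotations, ankle_offsets, knee_offsets,
                               foot_length, body_weight) {
  subject_geometry(
    rotation_lc_to_shank = average_rotation(rotations),
    r_ankle_to_lc = average_offset(ankle_offsets),
    r_knee_to_lc = average_offset(knee_offsets),
    foot_length = foot_length,
    body_weight = body_weight
  )
}

as_rotation_list <- function(samples) {
  if (is.array(samples) && length(dim(samples)) == 3) {
    stopifnot(dim(samples)[1] == 3, dim(samples)[2] == 3)
    samples <- lapply(seq_len(dim(samples)[3]), function(i) samples[, , i])
  }
  if (!is.list(samples)) stop("samples must be a list of matrices or a 3x3xn array")
  samples
}
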
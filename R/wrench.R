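## Core containers: time-stamped wrench streams and subject geometry.

#' Construct a wrench series
#'
#' A wrench series holds time-stamped 3-axis force and 3-axis moment samples
#' from a pylon-embedded six-axis load cell, tagged with the frame the vectors
#' are expressed in. Timestamps may be nonuniform (the load cell samples at a
#' jittery rate) but must be strictly increasing.
#'
#' Axis convention (shank frame): X anterior, Y proximal along the pylon,
#' Z to the subject's right. The sagittal plane is X-Y; the sagittal moment is
#' the Z component, plantarflexion (ground reaction force anterior to the
#' ankle) positive.
#'
#' @param time numeric vector of sample times, seconds, strictly increasing.
#' @param force n x 3 matrix of force samples, N.
#' @param moment n x 3 matrix of moment samples, N·m.
#' @param frame `"load_cell"` or `"shank"`.
#' @return object of class `wrench_series`.
#' @export
wrench_series <- function(time, force, moment, frame = c("load_cell", "shank")) {
  frame <- match.arg(frame)
  force <- as.matrix(force)
  moment <- as.matrix(moment)
  if (length(time) < 1) stop("empty wrench series")
  if (nrow(force) != length(time) || nrow(moment) != length(time)) {
    stop("force/moment sample counts must match the timestamps")
  }
  if (ncol(force) != 3 || ncol(moment) != 3) stop("force and moment must have 3 columns")
  if (!all(is.finite(time)) || !all(is.finite(force)) || !all(is.finite(moment))) {
    stop("all values must be finite")
  }
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps not strictly increasing at sample %d", bad[1] + 1))
  }
  dimnames(force) <- list(NULL, c("fx", "fy", "fz"))
  dimnames(moment) <- list(NULL, c("mx", "my", "mz"))
  structure(
    list(time = as.numeric(time), force = force, moment = moment, frame = frame),
    class = "wrench_series"
  )
}

#' @export
print.wrench_series <- function(x, ...) {
  cat(sprintf(
    "<wrench_series> %d samples, %.2f-%.2f s, frame: %s\n",
    length(x$time), x$time[1], x$time[length(x$time)], x$frame
  ))
  cat(sprintf(
    "  mean rate %.1f Hz, |F| range [%.1f, %.1f] N\n",
    (length(x$time) - 1) / diff(range(x$time)),
    sqrt(min(rowSums(x$force^2))), sqrt(max(rowSums(x$force^2)))
  ))
  invisible(x)
}

#' Number of samples in a wrench series
#' @param x a `wrench_series`.
#' @return integer sample count.
#' @export
n_samples <- function(x) length(x$time)

#' Construct subject geometry
#'
#' Per-subject geometric calibration: the definitive load-cell-to-shank
#' rotation, the vectors from each joint center (ankle, knee) to the load-cell
#' origin expressed in the shank frame, the prosthetic foot length used to
#' normalize DMAMA, and body weight used for event thresholds.
#'
#' @param rotation_lc_to_shank 3x3 rotation taking load-cell-frame vectors to
#'   the shank frame (orthonormal, det +1 within 1e-9 after projection).
#' @param r_ankle_to_lc,r_knee_to_lc numeric length-3 offset vectors, m, from
#'   the joint center to the load-cell origin (shank frame).
#' @param foot_length foot length, m (> 0).
#' @param body_weight body weight, N (> 0).
#' @return object of class `subject_geometry`.
#' @export
subject_geometry <- function(rotation_lc_to_shank, r_ankle_to_lc, r_knee_to_lc,
                             foot_length, body_weight) {
  check_rotation(rotation_lc_to_shank, tol = 1e-9)
  stopifnot(
    length(r_ankle_to_lc) == 3, all(is.finite(r_ankle_to_lc)),
    length(r_knee_to_lc) == 3, all(is.finite(r_knee_to_lc))
  )
  if (!is.finite(foot_length) || foot_length <= 0) stop("foot_length must be > 0")
  if (!is.finite(body_weight) || body_weight <= 0) stop("body_weight must be > 0")
  structure(
    list(
      rotation_lc_to_shank = rotation_lc_to_shank,
      r_ankle_to_lc = as.numeric(r_ankle_to_lc),
      r_knee_to_lc = as.numeric(r_knee_to_lc),
      foot_length = foot_length,
      body_weight = body_weight
    ),
    class = "subject_geometry"
  )
}

#' @export
print.subject_geometry <- function(x, ...) {
  ang <- rotation_distance(diag(3), x$rotation_lc_to_shank) * 180 / pi
  cat(sprintf(
    "<subject_geometry> foot %.3f m, weight %.0f N, LC-to-shank rotation %.2f deg\n",
    x$foot_length, x$body_weight, ang
  ))
  cat(sprintf(
    "  ankle->LC (%.3f, %.3f, %.3f) m; knee->LC (%.3f, %.3f, %.3f) m\n",
    x$r_ankle_to_lc[1], x$r_ankle_to_lc[2], x$r_ankle_to_lc[3],
    x$r_knee_to_lc[1], x$r_knee_to_lc[2], x$r_knee_to_lc[3]
  ))
  invisible(x)
}
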
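## DMAMA metric: quasi-static sagittal joint moments by moment transport and
## the per-stride impulse ratio, normalized to percent foot length.

#' Quasi-static sagittal joint moments from a shank-frame wrench
#'
#' Transports the measured load-cell wrench to the ankle and knee joint
#' centers: for each joint, the sagittal moment is the Z component of the
#' cross product of the joint-to-sensor lever arm with the sagittal-plane
#' load-cell force, plus the measured sagittal moment. Inertial terms are neglected (stance-phase segment accelerations are
#' low), so the load-cell force doubles as the ground reaction force.
#'
#' @param series a `wrench_series` in the shank frame.
#' @param geometry a `subject_geometry` with ankle and knee offset vectors.
#' @return object of class `joint_moment_series`: data.frame with `time`,
#'   `ankle_moment`, `knee_moment` (N·m, extensor positive), `fx`, `fy` (N).
#' @export
joint_moments <- function(series, geometry) {
  stopifnot(inherits(series, "wrench_series"), inherits(geometry, "subject_geometry"))
  if (series$frame != "shank") stop("joint moments require a shank-frame series")
  fx <- series$force[, 1]
  fy <- series$force[, 2]
  mz <- series$moment[, 3]
  transport <- function(r) {
    if (is.null(r) || length(r) != 3 || anyNA(r)) {
      stop("missing offset vector for requested joint")
    }
    r[1] * fy - r[2] * fx + mz # Z component of r x F_sagittal + M_sagittal
  }
  out <- data.frame(
    time = series$time,
    ankle_moment = transport(geometry$r_ankle_to_lc),
    knee_moment = transport(geometry$r_knee_to_lc),
    fx = fx,
    fy = fy
  )
  class(out) <- c("joint_moment_series", "data.frame")
  out
}

#' Per-stride DMAMA from a joint-moment series
#'
#' The dynamic mean ankle moment arm is the ratio of the stance-phase sagittal
#' ankle-moment impulse to the magnitude of the sagittal ground-reaction-force
#' impulse: trapezoidal integrals over `[heel_strike, toe_off]` on the raw
#' (nonuniform) measured timestamps, with the window endpoints interpolated.
#' The "magnitude of the force impulse" is the Euclidean norm of the vector
#' impulse (the norm of the integral, not the integral of the norm). The
#' resulting length is also reported as a percentage of the prosthetic foot
#' length.
#'
#' Strides whose force-impulse magnitude falls below `min_impulse` (1 N·s) are
#' flagged invalid rather than raising an error.
#'
#' @param moments a `joint_moment_series`.
#' @param segment one stride: any list/row with `heel_strike` and `toe_off`
#'   inside the series time range (e.g. one row of a `stride_table`).
#' @param geometry a `subject_geometry` (for the foot length).
#' @param min_impulse validity threshold on the force-impulse magnitude, N·s.
#' @return one-row data.frame of class `dmama_result`: `moment_impulse`
#'   (N·m·s), `force_impulse_magnitude` (N·s), `mean_ankle_moment` (N·m),
#'   `mean_sagittal_force` (N), `dmama_m` (m), `dmama_pct_foot`, `valid`.
#' @export
compute_dmama <- function(moments, segment, geometry, min_impulse = 1) {
  stopifnot(inherits(moments, "joint_moment_series"), inherits(geometry, "subject_geometry"))
  hs <- segment$heel_strike
  to <- segment$toe_off
  if (is.null(hs) || is.null(to) || hs >= to) stop("segment must have heel_strike < toe_off")
  tt <- moments$time
  if (hs < tt[1] || to > tt[length(tt)]) stop("segment lies outside the series time range")

  clip <- clip_window(tt, hs, to)
  tw <- clip$time
  J <- pracma::trapz(tw, clip$interp(moments$ankle_moment))
  Ix <- pracma::trapz(tw, clip$interp(moments$fx))
  Iy <- pracma::trapz(tw, clip$interp(moments$fy))
  I <- sqrt(Ix^2 + Iy^2)
  dur <- to - hs
  valid <- is.finite(I) && I >= min_impulse
  dmama_m <- if (I > 0) J / I else NA_real_
  out <- data.frame(
    stride_id = if (!is.null(segment$stride_id)) segment$stride_id else NA_integer_,
    moment_impulse = J,
    force_impulse_magnitude = I,
    mean_ankle_moment = J / dur,
    mean_sagittal_force = I / dur,
    dmama_m = dmama_m,
    dmama_pct_foot = 100 * dmama_m / geometry$foot_length,
    valid = valid
  )
  class(out) <- c("dmama_result", "data.frame")
  out
}

#' DMAMA for every stride of a segmented series
#'
#' Applies [compute_dmama()] to each row of a stride table, carrying the mode,
#' stiffness code, and exclusion flag through.
#'
#' @param moments a `joint_moment_series`.
#' @param strides a `stride_table` from [segment_strides()].
#' @param geometry a `subject_geometry`.
#' @return data.frame with one row per stride: stride metadata plus the
#'   `dmama_result` columns.
#' @export
dmama_table <- function(moments, strides, geometry) {
  res <- lapply(seq_len(nrow(strides)), function(i) {
    compute_dmama(moments, strides[i, ], geometry)
  })
  res <- do.call(rbind, res)
  cbind(
    strides[, c("stride_id", "heel_strike", "toe_off", "mode", "stiffness_code", "excluded")],
    res[, setdiff(names(res), "stride_id")],
    row.names = NULL
  )
}

#' Moving-average DMAMA over recent strides
#'
#' Trailing mean of `dmama_pct_foot` over the last `window` non-excluded,
#' valid strides — the smoothed control signal a stiffness controller would
#' act on rather than single-stride values.
#'
#' @param results data.frame with `dmama_pct_foot` and optionally `excluded`
#'   and `valid` columns, in stride order.
#' @param window number of strides in the trailing window (>= 1).
#' @return data.frame with `stride_id` (when present) and `dmama_smoothed`
#'   for each non-excluded valid stride; the first `window - 1` entries
#'   average over the strides available so far.
#' @export
moving_average_dmama <- function(results, window = 5) {
  if (window < 1) stop("window must be >= 1")
  keep <- rep(TRUE, nrow(results))
  if ("excluded" %in% names(results)) keep <- keep & !results$excluded
  if ("valid" %in% names(results)) keep <- keep & results$valid
  x <- results$dmama_pct_foot[keep]
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - window + 1):i])
  }, numeric(1))
  data.frame(
    stride_id = if ("stride_id" %in% names(results)) results$stride_id[keep] else seq_len(n),
    dmama_pct_foot = x,
    dmama_smoothed = sm
  )
}

# clipped integration window: raw samples inside [hs, to] plus interpolated
# endpoint values at hs and to exactly
clip_window <- function(tt, hs, to) {
  inside <- which(tt > hs & tt < to)
  tw <- c(hs, tt[inside], to)
  list(
    time = tw,
    interp = function(y) {
      c(
        stats::approx(tt, y, xout = hs)$y,
        y[inside],
        stats::approx(tt, y, xout = to)$y
      )
    }
  )
}
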
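## Stride pipeline: uniform resampling (classifier path only), gait-event
## detection from the sagittal force, and stride segmentation with
## transition exclusion.

#' Resample a wrench series onto a uniform grid
#'
#' Linear interpolation of every force/moment channel onto a uniform grid at
#' the requested rate, spanning the original time range. Used by the
#' classifier path to compensate for the load cell's nonuniform sampling; the
#' DMAMA path integrates on the raw measured timestamps instead.
#'
#' @param series a `wrench_series` (any frame).
#' @param rate target rate, Hz (> 0).
#' @return a `wrench_series` on the uniform grid, same frame.
#' @export
resample_uniform <- function(series, rate = 100) {
  stopifnot(inherits(series, "wrench_series"))
  if (rate <= 0) stop("rate must be > 0")
  if (length(series$time) < 2) stop("need at least 2 samples to resample")
  t0 <- series$time[1]
  t1 <- series$time[length(series$time)]
  grid <- t0 + seq(0, floor((t1 - t0) * rate)) / rate
  # rule = 2 guards the last grid point against floating-point overshoot
  interp <- function(y) stats::approx(series$time, y, xout = grid, rule = 2)$y
  wrench_series(
    time = grid,
    force = apply(series$force, 2, interp),
    moment = apply(series$moment, 2, interp),
    frame = series$frame
  )
}

#' Detect heel-strike and toe-off events from the sagittal force
#'
#' Thresholds the sagittal-plane force magnitude `sqrt(Fx^2 + Fy^2)` at 8
#' percent of body weight: an upward crossing marks heel strike, a downward
#' crossing toe-off. Event times are the first and last samples at or above
#' the threshold of each stance run. Debounce: runs separated by less than
#' `min_swing_s` are merged (threshold chatter), and merged runs shorter than
#' `min_stance_s` are discarded.
#'
#' @param series a `wrench_series` in the shank frame.
#' @param body_weight body weight, N (> 0).
#' @param threshold_frac threshold as a fraction of body weight (default 0.08).
#' @param min_stance_s minimum stance duration accepted, s.
#' @param min_swing_s minimum swing gap between stances, s.
#' @return data.frame with columns `heel_strike`, `toe_off` (s); zero rows if
#'   the signal never crosses the threshold.
#' @export
detect_events <- function(series, body_weight, threshold_frac = 0.08,
                          min_stance_s = 0.2, min_swing_s = 0.1) {
  stopifnot(inherits(series, "wrench_series"))
  if (series$frame != "shank") stop("event detection requires a shank-frame series")
  if (body_weight <= 0) stop("body_weight must be > 0")
  fmag <- sqrt(series$force[, 1]^2 + series$force[, 2]^2)
  above <- fmag >= threshold_frac * body_weight
  if (!any(above)) {
    return(data.frame(heel_strike = numeric(0), toe_off = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by a sub-debounce swing gap
  if (nrow(runs) > 1) {
    keep <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- series$time[runs$start[i]] - series$time[keep$end[nrow(keep)]]
      if (gap < min_swing_s) {
        keep$end[nrow(keep)] <- runs$end[i]
      } else {
        keep <- rbind(keep, runs[i, ])
      }
    }
    runs <- keep
  }
  hs <- series$time[runs$start]
  to <- series$time[runs$end]
  ok <- (to - hs) >= min_stance_s
  data.frame(heel_strike = hs[ok], toe_off = to[ok])
}

#' Segment strides and attach labels
#'
#' Builds one stride segment per detected stance, assigns the locomotion mode
#' by majority vote over the stance's per-sample labels, and flags segments
#' for exclusion when the stance spans more than one mode or contains samples
#' flagged as transition (transition steps between locomotion modes are
#' excluded from analysis).
#'
#' @param events data.frame from [detect_events()] (`heel_strike`, `toe_off`).
#' @param labels data.frame with per-sample `time`, `mode`, and optionally
#'   `transition` (logical) covering the full event time range.
#' @param stiffness_code optional stiffness code attached to every segment.
#' @return data.frame of class `stride_table`: `stride_id`, `heel_strike`,
#'   `toe_off`, `mode`, `stiffness_code`, `excluded`.
#' @export
segment_strides <- function(events, labels, stiffness_code = NA_integer_) {
  stopifnot(is.data.frame(events), is.data.frame(labels))
  if (nrow(events) == 0) {
    out <- data.frame(
      stride_id = integer(0), heel_strike = numeric(0), toe_off = numeric(0),
      mode = character(0), stiffness_code = integer(0), excluded = logical(0),
      stringsAsFactors = FALSE
    )
    class(out) <- c("stride_table", "data.frame")
    return(out)
  }
  if (any(events$heel_strike < min(labels$time)) ||
      any(events$toe_off > max(labels$time))) {
    stop("labels do not cover the event time range")
  }
  has_trans <- "transition" %in% names(labels)
  n <- nrow(events)
  mode <- character(n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    in_stance <- labels$time >= events$heel_strike[i] &
      labels$time <= events$toe_off[i]
    mm <- labels$mode[in_stance]
    tab <- table(mm)
    mode[i] <- names(tab)[which.max(tab)]
    excluded[i] <- length(tab) > 1 ||
      (has_trans && any(labels$transition[in_stance]))
  }
  out <- data.frame(
    stride_id = seq_len(n),
    heel_strike = events$heel_strike,
    toe_off = events$toe_off,
    mode = mode,
    stiffness_code = stiffness_code,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stride_table", "data.frame")
  out
}
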
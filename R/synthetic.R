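## Synthetic gait-session generator: load-cell-frame wrench streams with
## per-stride ground-truth DMAMA, per-sample mode labels, and true geometry.
##
## The generator emulates the statistical structure the downstream analyses
## assume: a linear DMAMA response to stiffness and incline with a negative
## interaction, subject-specific intercepts, stride-to-stride noise, sensor
## noise, and sampling-rate jitter. Waveform shapes are a stylized stance
## model (two-peak axial load, S-shaped anterior-posterior shear, squared
## half-sine ankle-moment envelope); only the impulse ratio is constrained to
## match the drawn per-stride DMAMA target.

# per-mode stance shape parameters: a1/a3 axial harmonics, cx shear amplitude
# (fractions of body weight), fz out-of-plane force fraction, mx/my frontal and
# transverse moment amplitudes (N.m), dur stance-duration scale. Values are
# distinct per mode so locomotion classes are separable; stairs use a
# qualitatively different (single-peak) loading profile.
mode_shapes <- function() {
  data.frame(
    mode = c("level", "up_ramp", "down_ramp", "up_stairs", "down_stairs"),
    a1 = c(1.00, 1.00, 1.05, 0.95, 1.10),
    a3 = c(0.25, 0.18, 0.30, -0.10, -0.20),
    cx = c(0.16, 0.22, 0.10, 0.06, 0.04),
    fz = c(0.03, 0.05, 0.02, 0.08, 0.10),
    mx = c(2, 4, 6, 8, 10),
    my = c(1, 2, 3, 5, 6),
    dur = c(1.00, 1.05, 0.95, 1.25, 1.15),
    stringsAsFactors = FALSE
  )
}

# sagittal-force floor at stance edges, fraction of body weight; keeps the
# whole stance above the 8%-BW event threshold so the detected stance window
# equals the generated one
stance_edge_floor <- 0.10

locomotion_modes <- function() c("down_ramp", "level", "up_ramp", "down_stairs", "up_stairs")

#' Configuration for a synthetic gait session
#'
#' Bundles and validates every parameter of the generative model. Defaults
#' emulate the study conditions the analyses are designed for: 4 subjects,
#' roughly 50 level-ground and 11 strides per other mode per stiffness trial,
#' three stiffness settings coded 0/1/2, ramp inclines of -5/0/+5 degrees,
#' DMAMA sensitivities of 3.01 percent foot length per stiffness increment and
#' 0.413 per degree incline with a -0.145 interaction, 3 percent-foot-length
#' stride noise, and load-cell sampling jitter of 149.9 +/- 38.5 Hz (floored
#' at 50 Hz).
#'
#' @param subjects number of subjects (>= 1).
#' @param strides_per_condition named integer vector, strides per mode per
#'   stiffness trial. Names must be locomotion modes (`down_ramp`, `level`,
#'   `up_ramp`, `down_stairs`, `up_stairs`).
#' @param stiffness_levels named integer vector of stiffness codes; codes must
#'   be consecutive integers starting at 0 (default low/medium/high = 0/1/2).
#' @param incline_deg named vector of ground incline per ramp/level mode,
#'   degrees. Stairs carry no incline and contribute 0 to the incline term.
#' @param beta0_subject per-subject DMAMA intercepts, percent foot length
#'   (recycled to `subjects`).
#' @param beta_stiffness DMAMA sensitivity to stiffness, percent foot length
#'   per stiffness increment.
#' @param beta_incline DMAMA sensitivity to incline, percent foot length per
#'   degree.
#' @param beta_interaction interaction coefficient, percent foot length per
#'   (increment x degree).
#' @param stride_noise_sd stride-to-stride DMAMA noise SD, percent foot length.
#' @param sample_rate_mean_hz,sample_rate_sd_hz,sample_rate_floor_hz sampling
#'   jitter model: per-sample rates are drawn from a normal truncated below at
#'   the floor; intervals are the reciprocals.
#' @param sensor_noise_sd additive load-cell noise SD, applied to forces (N)
#'   and moments (N·m) in the load-cell frame.
#' @param stance_duration_s,swing_duration_s nominal stance and swing
#'   durations, s (> 0); stance is scaled per mode.
#' @param foot_length_m prosthetic foot length, m (> 0; recycled per subject).
#' @param body_weight_n body weight, N (> 0; recycled per subject).
#' @param transition_strides insert one flagged transition stride (mode label
#'   switches mid-stance) at each mode-block boundary.
#' @param seed integer RNG seed; identical config + seed reproduces
#'   bit-identical output.
#' @return object of class `session_config`.
#' @export
session_config <- function(subjects = 4,
                           strides_per_condition = c(
                             level = 50, up_ramp = 11, down_ramp = 11,
                             up_stairs = 11, down_stairs = 11
                           ),
                           stiffness_levels = c(low = 0L, medium = 1L, high = 2L),
                           incline_deg = c(down_ramp = -5, level = 0, up_ramp = 5),
                           beta0_subject = c(8, 10, 12, 14),
                           beta_stiffness = 3.01,
                           beta_incline = 0.413,
                           beta_interaction = -0.145,
                           stride_noise_sd = 3,
                           sample_rate_mean_hz = 149.9,
                           sample_rate_sd_hz = 38.5,
                           sample_rate_floor_hz = 50,
                           sensor_noise_sd = 0.5,
                           stance_duration_s = 0.7,
                           swing_duration_s = 0.5,
                           foot_length_m = 0.24,
                           body_weight_n = 883,
                           transition_strides = TRUE,
                           seed = 1L) {
  if (subjects < 1) stop("need at least one subject")
  if (is.null(names(strides_per_condition)) ||
      !all(names(strides_per_condition) %in% locomotion_modes())) {
    stop("strides_per_condition must be named by locomotion mode")
  }
  if (any(strides_per_condition < 1)) stop("all stride counts must be >= 1")
  codes <- sort(as.integer(stiffness_levels))
  if (!identical(codes, seq(0L, length(codes) - 1L))) {
    stop("stiffness codes must be consecutive integers starting at 0")
  }
  if (stride_noise_sd < 0 || sensor_noise_sd < 0 || sample_rate_sd_hz < 0) {
    stop("noise SDs must be >= 0")
  }
  if (stance_duration_s <= 0 || swing_duration_s <= 0) {
    stop("stance and swing durations must be > 0")
  }
  if (sample_rate_mean_hz <= 0 || sample_rate_floor_hz <= 0) {
    stop("sampling rates must be > 0")
  }
  if (any(foot_length_m <= 0)) stop("foot length must be > 0")
  if (any(body_weight_n <= 0)) stop("body weight must be > 0")
  cfg <- list(
    subjects = as.integer(subjects),
    strides_per_condition = strides_per_condition,
    stiffness_levels = stiffness_levels,
    incline_deg = incline_deg,
    beta0_subject = rep_len(beta0_subject, subjects),
    beta_stiffness = beta_stiffness,
    beta_incline = beta_incline,
    beta_interaction = beta_interaction,
    stride_noise_sd = stride_noise_sd,
    sample_rate_mean_hz = sample_rate_mean_hz,
    sample_rate_sd_hz = sample_rate_sd_hz,
    sample_rate_floor_hz = sample_rate_floor_hz,
    sensor_noise_sd = sensor_noise_sd,
    stance_duration_s = stance_duration_s,
    swing_duration_s = swing_duration_s,
    foot_length_m = rep_len(foot_length_m, subjects),
    body_weight_n = rep_len(body_weight_n, subjects),
    transition_strides = isTRUE(transition_strides),
    seed = as.integer(seed)
  )
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "<session_config> %d subjects x %d stiffness levels, %d strides/trial, seed %d\n",
    x$subjects, length(x$stiffness_levels), sum(x$strides_per_condition), x$seed
  ))
  invisible(x)
}

# Deterministic plan shared by generate_session() and simulate_dmama_table():
# seeds the RNG, draws true geometry per subject, then the per-stride target
# DMAMA table. Any signal-level draws happen afterwards, so the target table
# is identical whether or not waveforms are synthesized.
session_plan <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  geometry <- lapply(seq_len(config$subjects), function(s) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 5, 15) * pi / 180
    subject_geometry(
      rotation_lc_to_shank = vector_to_rotation(ax * ang),
      r_ankle_to_lc = c(
        stats::runif(1, -0.02, 0.02), stats::runif(1, 0.30, 0.38),
        stats::runif(1, -0.01, 0.01)
      ),
      r_knee_to_lc = c(
        stats::runif(1, -0.02, 0.02), -stats::runif(1, 0.10, 0.16),
        stats::runif(1, -0.01, 0.01)
      ),
      foot_length = config$foot_length_m[s],
      body_weight = config$body_weight_n[s]
    )
  })

  block_order <- intersect(
    c("level", "up_ramp", "down_ramp", "up_stairs", "down_stairs"),
    names(config$strides_per_condition)
  )
  rows <- list()
  for (s in seq_len(config$subjects)) {
    for (k in seq_along(config$stiffness_levels)) {
      code <- as.integer(config$stiffness_levels[k])
      modes <- character(0)
      trans <- logical(0)
      for (b in seq_along(block_order)) {
        m <- block_order[b]
        if (b > 1 && config$transition_strides) {
          modes <- c(modes, m)
          trans <- c(trans, TRUE)
        }
        n <- config$strides_per_condition[[m]]
        modes <- c(modes, rep(m, n))
        trans <- c(trans, rep(FALSE, n))
      }
      incl <- ifelse(modes %in% names(config$incline_deg),
        config$incline_deg[modes], 0
      )
      mu <- config$beta0_subject[s] + config$beta_stiffness * code +
        config$beta_incline * incl + config$beta_interaction * code * incl
      target <- mu + stats::rnorm(length(mu), 0, config$stride_noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s,
        stiffness = names(config$stiffness_levels)[k],
        stiffness_code = code,
        mode = modes,
        incline_deg = as.numeric(incl),
        transition = trans,
        target_dmama_pct = target,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  truth$stride_id <- seq_len(nrow(truth))
  list(geometry = geometry, truth = truth)
}

#' Draw per-stride DMAMA targets from the generative model
#'
#' Returns the ground-truth stride table (subject, stiffness code, mode,
#' incline, transition flag, target DMAMA in percent foot length) that
#' [generate_session()] would embed in the same config and seed, without
#' synthesizing waveforms. Used for statistical parameter-recovery studies
#' where only the stride-level DMAMA draws matter.
#'
#' @param config a `session_config`.
#' @return data.frame, one row per stride.
#' @export
simulate_dmama_table <- function(config) {
  session_plan(config)$truth
}

#' Generate a synthetic gait session
#'
#' Synthesizes load-cell-frame wrench streams for every (subject, stiffness)
#' trial, with per-sample mode labels and per-stride ground truth. For each
#' stride, stance waveforms are built in the shank frame — a two-peak axial
#' ground reaction profile with a 10 percent body-weight floor at the stance
#' edges, an S-shaped anterior-posterior shear, and a squared-half-sine
#' sagittal ankle-moment waveform scaled so the ratio of ankle-moment impulse
#' to sagittal-force impulse magnitude equals the stride's drawn DMAMA target.
#' The load-cell wrench is obtained by transporting the moment to the sensor
#' (sensor moment = ankle moment minus the lever-arm cross product), rotating
#' with the inverse of the true load-cell-to-shank rotation, adding sensor
#' noise, and sampling at jittered intervals (with a sample placed exactly at
#' each stance boundary).
#'
#' @param config a `session_config`.
#' @param geometry optional list of `subject_geometry` (one per subject)
#'   overriding the randomly drawn true geometry; the per-stride DMAMA draws
#'   are unaffected.
#' @return object of class `gait_session`: list with `trials` (each holding
#'   `subject`, `stiffness`, `stiffness_code`, `series` (a `wrench_series`,
#'   load-cell frame), `labels` (per-sample data.frame: time, mode,
#'   transition)), `geometry` (list of true `subject_geometry` per subject),
#'   `truth` (per-stride ground-truth data.frame with heel-strike/toe-off
#'   times), and `config`.
#' @export
generate_session <- function(config, geometry = NULL) {
  plan <- session_plan(config)
  if (!is.null(geometry)) {
    stopifnot(length(geometry) == config$subjects)
    plan$geometry <- geometry
  }
  shapes <- mode_shapes()
  rownames(shapes) <- shapes$mode
  trials <- list()
  truth <- plan$truth
  truth$hs_time_s <- NA_real_
  truth$to_time_s <- NA_real_

  trial_keys <- unique(truth[, c("subject", "stiffness", "stiffness_code")])
  for (i in seq_len(nrow(trial_keys))) {
    s <- trial_keys$subject[i]
    geom <- plan$geometry[[s]]
    R <- geom$rotation_lc_to_shank
    bw <- geom$body_weight
    idx <- which(truth$subject == s & truth$stiffness_code == trial_keys$stiffness_code[i])

    t_cursor <- 0
    times <- list()
    F_sh <- list()
    M_sh <- list()
    lab_mode <- list()
    lab_trans <- list()
    prev_mode <- truth$mode[idx[1]]

    for (j in seq_along(idx)) {
      row <- idx[j]
      mode <- truth$mode[row]
      sh <- shapes[mode, ]
      T_st <- config$stance_duration_s * sh$dur
      t0 <- t_cursor + config$swing_duration_s
      t1 <- t0 + T_st

      # lead-in swing (open interval, next stance starts exactly at t0)
      tw <- jitter_times(
        t_cursor, t0, config$sample_rate_mean_hz,
        config$sample_rate_sd_hz, config$sample_rate_floor_hz,
        include_start = j == 1, include_end = FALSE
      )
      if (length(tw)) {
        times[[length(times) + 1]] <- tw
        F_sh[[length(F_sh) + 1]] <- matrix(0, length(tw), 3)
        M_sh[[length(M_sh) + 1]] <- matrix(0, length(tw), 3)
        # swing samples labeled with the upcoming stride's pre-switch mode
        lab_mode[[length(lab_mode) + 1]] <- rep(
          if (truth$transition[row]) prev_mode else mode, length(tw)
        )
        lab_trans[[length(lab_trans) + 1]] <- rep(FALSE, length(tw))
      }

      ts <- jitter_times(
        t0, t1, config$sample_rate_mean_hz,
        config$sample_rate_sd_hz, config$sample_rate_floor_hz,
        include_start = TRUE, include_end = TRUE
      )
      u <- (ts - t0) / T_st
      w <- stance_wrench_shank(
        u, T_st, sh, bw, geom,
        target_m = truth$target_dmama_pct[row] / 100 * geom$foot_length
      )
      times[[length(times) + 1]] <- ts
      F_sh[[length(F_sh) + 1]] <- w$force
      M_sh[[length(M_sh) + 1]] <- w$moment
      if (truth$transition[row]) {
        lab_mode[[length(lab_mode) + 1]] <- ifelse(u < 0.5, prev_mode, mode)
      } else {
        lab_mode[[length(lab_mode) + 1]] <- rep(mode, length(ts))
      }
      lab_trans[[length(lab_trans) + 1]] <- rep(truth$transition[row], length(ts))

      truth$hs_time_s[row] <- t0
      truth$to_time_s[row] <- t1
      t_cursor <- t1
      prev_mode <- mode
    }
    # trailing swing so the last toe-off is followed by sub-threshold data
    tw <- jitter_times(
      t_cursor, t_cursor + config$swing_duration_s,
      config$sample_rate_mean_hz, config$sample_rate_sd_hz,
      config$sample_rate_floor_hz,
      include_start = FALSE, include_end = TRUE
    )
    times[[length(times) + 1]] <- tw
    F_sh[[length(F_sh) + 1]] <- matrix(0, length(tw), 3)
    M_sh[[length(M_sh) + 1]] <- matrix(0, length(tw), 3)
    lab_mode[[length(lab_mode) + 1]] <- rep(prev_mode, length(tw))
    lab_trans[[length(lab_trans) + 1]] <- rep(FALSE, length(tw))

    tt <- unlist(times)
    Fm <- do.call(rbind, F_sh)
    Mm <- do.call(rbind, M_sh)
    # shank -> load cell with the inverse of the true rotation, then noise
    F_lc <- Fm %*% R
    M_lc <- Mm %*% R
    if (config$sensor_noise_sd > 0) {
      F_lc <- F_lc + stats::rnorm(length(F_lc), 0, config$sensor_noise_sd)
      M_lc <- M_lc + stats::rnorm(length(M_lc), 0, config$sensor_noise_sd)
    }
    trials[[i]] <- list(
      subject = s,
      stiffness = trial_keys$stiffness[i],
      stiffness_code = trial_keys$stiffness_code[i],
      series = wrench_series(tt, F_lc, M_lc, frame = "load_cell"),
      labels = data.frame(
        time = tt, mode = unlist(lab_mode), transition = unlist(lab_trans),
        stringsAsFactors = FALSE
      )
    )
  }
  structure(
    list(trials = trials, geometry = plan$geometry, truth = truth, config = config),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf(
    "<gait_session> %d trials (%d subjects), %d strides (%d transition), seed %d\n",
    length(x$trials), x$config$subjects, nrow(x$truth),
    sum(x$truth$transition), x$config$seed
  ))
  invisible(x)
}

#' Analytic stance waveforms in the shank frame
#'
#' Evaluates the generator's stance model at arbitrary times: forces, sensor
#' moments (with the sagittal channel set so moment transport recovers the
#' ankle moment exactly), and the underlying ankle-moment waveform. The
#' impulse ratio of the returned waveforms over a full stance equals
#' `target_dmama_pct` of the foot length by construction. Intended for
#' integration-accuracy studies against arbitrarily fine time grids.
#'
#' @param mode locomotion mode name.
#' @param times sample times within the stance, s, in `[0, stance_duration]`.
#' @param stance_duration stance duration, s.
#' @param geometry a `subject_geometry` (body weight, ankle offset, foot
#'   length).
#' @param target_dmama_pct the stride's DMAMA target, percent foot length.
#' @return list with `force` and `moment` (n x 3, shank frame) and
#'   `ankle_moment` (the generating waveform, N·m).
#' @export
stance_waveforms <- function(mode, times, stance_duration, geometry,
                             target_dmama_pct) {
  sh <- mode_shapes()
  sh <- sh[sh$mode == mode, ]
  if (!nrow(sh)) stop(sprintf("unknown mode '%s'", mode))
  w <- stance_wrench_shank(
    times / stance_duration, stance_duration, sh, geometry$body_weight,
    geometry, target_m = target_dmama_pct / 100 * geometry$foot_length
  )
  w
}

# shank-frame stance wrench at normalized times u in [0, 1]; the sagittal
# moment channel is set so the ankle moment recovered by transport equals the
# target-scaled envelope exactly
stance_wrench_shank <- function(u, T_st, sh, bw, geom, target_m) {
  fy <- bw * (stance_edge_floor + sh$a1 * sin(pi * u) + sh$a3 * sin(3 * pi * u))
  fx <- -sh$cx * bw * sin(2 * pi * u)
  fz <- sh$fz * bw * sin(pi * u)
  # analytic sagittal impulse of the stance: shear integrates to zero
  iy <- bw * T_st * (stance_edge_floor + 2 * sh$a1 / pi + 2 * sh$a3 / (3 * pi))
  m_scale <- target_m * iy / (T_st / 2) # integral of sin^2(pi u) over stance = T/2
  m_ankle <- m_scale * sin(pi * u)^2
  r <- geom$r_ankle_to_lc
  mz <- m_ankle - (r[1] * fy - r[2] * fx)
  mx <- sh$mx * sin(pi * u)
  my <- sh$my * sin(2 * pi * u)
  list(
    force = cbind(fx, fy, fz), moment = cbind(mx, my, mz),
    ankle_moment = m_ankle
  )
}

# jittered sample times covering [t0, t1]: per-sample rates from a normal
# truncated below at floor_hz, intervals are reciprocals
jitter_times <- function(t0, t1, mean_hz, sd_hz, floor_hz,
                         include_start = TRUE, include_end = TRUE) {
  span <- t1 - t0
  n_guess <- ceiling(span * mean_hz * 1.5) + 10
  dt <- 1 / rtruncnorm_lower(n_guess, mean_hz, sd_hz, floor_hz)
  while (sum(dt) < span) {
    dt <- c(dt, 1 / rtruncnorm_lower(n_guess, mean_hz, sd_hz, floor_hz))
  }
  ts <- t0 + cumsum(dt)
  ts <- ts[ts < t1 - 1e-4]
  out <- c(if (include_start) t0, ts, if (include_end) t1)
  out
}

# normal truncated below at `lower`, by rejection (vectorized)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) {
    return(rep(max(mean, lower), n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a calibration trial
#'
#' Produces paired noisy observations of a subject's true load-cell-to-shank
#' rotation and joint-to-sensor offset vectors, emulating repeated
#' motion-capture samples of the mounting geometry. Each rotation sample is
#' the truth composed with a random small rotation (uniformly random axis,
#' normal angle with SD `orientation_noise_deg`); each offset sample adds
#' isotropic normal noise.
#'
#' @param geometry true `subject_geometry`.
#' @param n_samples number of paired samples (>= 1).
#' @param orientation_noise_deg SD of the perturbation angle, degrees (>= 0).
#' @param offset_noise_m SD of offset noise per component, m (>= 0).
#' @param seed integer RNG seed.
#' @return list with `rotations` (list of 3x3 matrices), `ankle_offsets` and
#'   `knee_offsets` (n x 3 matrices).
#' @export
generate_calibration_trial <- function(geometry, n_samples = 300,
                                       orientation_noise_deg = 1,
                                       offset_noise_m = 0.001, seed = 1L) {
  stopifnot(inherits(geometry, "subject_geometry"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (orientation_noise_deg < 0 || offset_noise_m < 0) {
    stop("noise magnitudes must be >= 0")
  }
  set.seed(as.integer(seed))
  sd_rad <- orientation_noise_deg * pi / 180
  rotations <- lapply(seq_len(n_samples), function(i) {
    if (sd_rad == 0) {
      geometry$rotation_lc_to_shank
    } else {
      geometry$rotation_lc_to_shank %*% random_small_rotation(stats::rnorm(1, 0, sd_rad))
    }
  })
  noise <- function(true_v) {
    m <- matrix(rep(true_v, each = n_samples), n_samples, 3)
    if (offset_noise_m > 0) m <- m + stats::rnorm(3 * n_samples, 0, offset_noise_m)
    m
  }
  list(
    rotations = rotations,
    ankle_offsets = noise(geometry$r_ankle_to_lc),
    knee_offsets = noise(geometry$r_knee_to_lc)
  )
}
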
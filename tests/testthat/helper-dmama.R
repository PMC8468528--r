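# Shared fixtures, all built in code.

# small but complete session config (all five modes, both drivers varying)
tiny_config <- function(seed = 11, ...) {
  session_config(
    subjects = 2,
    strides_per_condition = c(
      level = 6, up_ramp = 4, down_ramp = 4, up_stairs = 4, down_stairs = 4
    ),
    seed = seed,
    ...
  )
}

# deterministic non-trivial rotation: 20 degrees about a fixed skew axis
fixture_rotation <- function(angle_deg = 20) {
  ax <- c(1, 2, 3) / sqrt(14)
  vector_to_rotation(ax * angle_deg * pi / 180)
}

fixture_geometry <- function(rotation = fixture_rotation(),
                             r_ankle = c(0.01, 0.34, 0.0),
                             r_knee = c(-0.01, -0.12, 0.0),
                             foot_length = 0.24, body_weight = 883) {
  subject_geometry(rotation, r_ankle, r_knee, foot_length, body_weight)
}

identity_geometry <- function(foot_length = 0.24, body_weight = 883) {
  subject_geometry(diag(3), c(0, 0, 0), c(0, -0.12, 0), foot_length, body_weight)
}

# wrench series with a constant vertical force at a fixed anterior moment arm:
# the analytically forced constant-DMAMA case
constant_arm_series <- function(arm_m = 0.06, force_n = 700, rate = 100,
                                duration = 0.8, geometry = identity_geometry()) {
  tt <- seq(0, duration, by = 1 / rate)
  n <- length(tt)
  r <- geometry$r_ankle_to_lc
  fy <- rep(force_n, n)
  fx <- rep(0, n)
  # sensor sagittal moment such that transport to the ankle gives arm * F
  mz <- arm_m * fy - (r[1] * fy - r[2] * fx)
  wrench_series(tt, cbind(fx, fy, 0), cbind(0, 0, mz), frame = "shank")
}

# chordal mean of rotations: SVD projection of the element-wise matrix mean
# (independent oracle for rotation averaging)
chordal_mean <- function(rotations) {
  M <- Reduce(`+`, rotations) / length(rotations)
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

# stride-level DMAMA table drawn straight from a linear model (for the
# sensitivity-fit unit tests)
linear_dmama_table <- function(subjects = 1:4, codes = 0:2, inclines = c(-5, 0, 5),
                               n_per = 11, b0 = c(8, 10, 12, 14), bs = 3, bi = 0.4,
                               bint = 0, noise_sd = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(
    subject = subjects, stiffness_code = codes, incline_deg = inclines,
    rep = seq_len(n_per)
  )
  g$mode <- c(`-5` = "down_ramp", `0` = "level", `5` = "up_ramp")[as.character(g$incline_deg)]
  g$dmama_pct_foot <- b0[g$subject] + bs * g$stiffness_code + bi * g$incline_deg +
    bint * g$stiffness_code * g$incline_deg +
    rnorm(nrow(g), 0, noise_sd)
  g
}
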
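# Synthetic gait-session generator: determinism, forward-inverse consistency,
# the impulse-ratio construction, the jitter model, and calibration trials.

test_that("identical config and seed reproduce bit-identical sessions", {
  cfg <- tiny_config(seed = 21)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a, b)
})

test_that("the stride-table shortcut matches the session's embedded ground truth", {
  cfg <- tiny_config(seed = 5)
  tab <- simulate_dmama_table(cfg)
  ses <- generate_session(cfg)
  expect_identical(
    tab$target_dmama_pct,
    ses$truth$target_dmama_pct
  )
  expect_identical(tab$mode, ses$truth$mode)
})

test_that("ground-truth targets follow the generative linear model exactly", {
  cfg <- tiny_config(seed = 13, stride_noise_sd = 0)
  tab <- simulate_dmama_table(cfg)
  mu <- cfg$beta0_subject[tab$subject] +
    cfg$beta_stiffness * tab$stiffness_code +
    cfg$beta_incline * tab$incline_deg +
    cfg$beta_interaction * tab$stiffness_code * tab$incline_deg
  expect_equal(tab$target_dmama_pct, mu, tolerance = 1e-12)
  # stairs carry no incline contribution
  expect_true(all(tab$incline_deg[grepl("stairs", tab$mode)] == 0))
})

test_that("identity rotation and zero ankle offset leave the load-cell frame equal to the shank frame", {
  cfg <- tiny_config(seed = 9, sensor_noise_sd = 0)
  geoms <- rep(list(identity_geometry()), cfg$subjects)
  ses_id <- generate_session(cfg, geometry = geoms)
  R <- fixture_rotation()
  geoms_rot <- rep(list(fixture_geometry(rotation = R, r_ankle = c(0, 0, 0))), cfg$subjects)
  ses_rot <- generate_session(cfg, geometry = geoms_rot)
  # same plan, so rotating the second session back must reproduce the first
  a <- ses_id$trials[[1]]$series
  b <- to_shank_frame(ses_rot$trials[[1]]$series, geoms_rot[[1]])
  expect_equal(a$time, b$time)
  expect_equal(a$force, b$force, tolerance = 1e-12)
  expect_equal(a$moment, b$moment, tolerance = 1e-12)
})

test_that("impulse-ratio construction holds on every noise-free stride", {
  cfg <- tiny_config(seed = 31, sensor_noise_sd = 0)
  geoms <- rep(list(identity_geometry()), cfg$subjects)
  ses <- generate_session(cfg, geometry = geoms)
  tr <- ses$trials[[1]]
  gt <- ses$truth[
    ses$truth$subject == tr$subject &
      ses$truth$stiffness_code == tr$stiffness_code & !ses$truth$transition,
  ]
  for (i in seq_len(nrow(gt))) {
    keep <- tr$series$time >= gt$hs_time_s[i] & tr$series$time <= gt$to_time_s[i]
    tt <- tr$series$time[keep]
    # zero offsets: the sensor Mz is the ankle moment itself
    J <- pracma::trapz(tt, tr$series$moment[keep, 3])
    I <- sqrt(
      pracma::trapz(tt, tr$series$force[keep, 1])^2 +
        pracma::trapz(tt, tr$series$force[keep, 2])^2
    )
    d_pct <- 100 * (J / I) / identity_geometry()$foot_length
    expect_lt(abs(d_pct - gt$target_dmama_pct[i]) / abs(gt$target_dmama_pct[i]), 1e-3)
  }
})

test_that("moment transport round trip reproduces the generating ankle moment", {
  cfg <- tiny_config(seed = 17, sensor_noise_sd = 0)
  geom <- fixture_geometry()
  ses <- generate_session(cfg, geometry = rep(list(geom), cfg$subjects))
  ses_id <- generate_session(cfg, geometry = rep(list(identity_geometry()), cfg$subjects))
  shank <- to_shank_frame(ses$trials[[1]]$series, geom)
  jm <- joint_moments(shank, geom)
  # with identity geometry the sensor Mz channel IS the ankle moment
  expect_equal(jm$ankle_moment, ses_id$trials[[1]]$series$moment[, 3], tolerance = 1e-9)
})

test_that("timestamps are strictly increasing in every trial", {
  ses <- generate_session(tiny_config(seed = 2))
  for (tr in ses$trials) {
    expect_true(all(diff(tr$series$time) > 0))
  }
})

test_that("sampling jitter matches the truncated-normal rate model", {
  set.seed(1)
  n <- 5000
  rates <- dmama:::rtruncnorm_lower(n, 149.9, 38.5, 50)
  expect_true(all(rates >= 50))
  # closed-form mean of a normal truncated below at a
  a <- (50 - 149.9) / 38.5
  mu_trunc <- 149.9 + 38.5 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(rates) - mu_trunc), 3 * 38.5 / sqrt(n))
  # realized sampling intervals are reciprocals of such rates
  ts <- dmama:::jitter_times(0, 30, 149.9, 38.5, 50)
  expect_true(all(diff(ts) > 0))
  expect_lt(abs(mean(1 / diff(ts)) - mu_trunc), 4 * 38.5 / sqrt(length(ts)))
})

test_that("transition strides are flagged and inserted at mode boundaries", {
  cfg <- tiny_config(seed = 4)
  ses <- generate_session(cfg)
  tr1 <- ses$truth[ses$truth$subject == 1 & ses$truth$stiffness_code == 0, ]
  # one transition per boundary between the five mode blocks
  expect_identical(sum(tr1$transition), 4L)
  # a transition stride's per-sample labels change mid-stance
  t_row <- tr1[tr1$transition, ][1, ]
  lab <- ses$trials[[1]]$labels
  in_stance <- lab$time >= t_row$hs_time_s & lab$time <= t_row$to_time_s
  expect_identical(length(unique(lab$mode[in_stance])), 2L)
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(subjects = 0), "at least one subject")
  expect_error(session_config(strides_per_condition = c(level = 0)), ">= 1")
  expect_error(session_config(stride_noise_sd = -1), ">= 0")
  expect_error(session_config(stance_duration_s = 0), "> 0")
  expect_error(session_config(foot_length_m = -0.2), "foot length")
  expect_error(session_config(body_weight_n = 0), "body weight")
  expect_error(session_config(stiffness_levels = c(low = 1L, high = 2L)), "consecutive")
})

test_that("calibration trials honor their noise parameters", {
  geom <- fixture_geometry()
  # zero noise: every sample equals the truth
  trial <- generate_calibration_trial(geom, 5, 0, 0, seed = 1)
  for (R in trial$rotations) {
    expect_lt(rotation_distance(R, geom$rotation_lc_to_shank), 1e-12)
  }
  expect_equal(unname(trial$ankle_offsets[1, ]), geom$r_ankle_to_lc)
  # a single sample passes through unchanged
  one <- generate_calibration_trial(geom, 1, 0, 0, seed = 1)
  expect_identical(length(one$rotations), 1L)
  expect_equal(one$rotations[[1]], geom$rotation_lc_to_shank)
  # parameter validation
  expect_error(generate_calibration_trial(geom, 0), "n_samples")
  expect_error(generate_calibration_trial(geom, 10, -1, 0), ">= 0")
  # 300 samples at 1 degree noise: averaging recovers the truth within 0.5 deg
  trial <- generate_calibration_trial(geom, 300, 1, 0.001, seed = 2)
  expect_lt(
    rotation_distance(average_rotation(trial$rotations), geom$rotation_lc_to_shank),
    0.5 * pi / 180
  )
})
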
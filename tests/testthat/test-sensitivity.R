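# Sensitivity analysis: pooled and per-subject regressions, cross-fit R^2,
# and the stiffness x incline interaction model.

test_that("exact linear data are recovered with slope 3 and R^2 = 1", {
  tab <- linear_dmama_table(bs = 3, bi = 0, noise_sd = 0)
  fit <- suppressWarnings(fit_subject_independent(tab, "stiffness", stratum = "level"))
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-6)
  # per-subject intercepts recovered exactly
  expect_equal(unname(fit$intercepts), c(8, 10, 12, 14), tolerance = 1e-10)
})

test_that("offset intercepts do not bias the pooled slope", {
  tab <- linear_dmama_table(
    subjects = 1:2, b0 = c(5, 25), bs = 2.5, bi = 0, noise_sd = 0
  )
  fit <- suppressWarnings(fit_subject_independent(tab, "stiffness", stratum = "level"))
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
})

test_that("the pooled slope obeys the Frisch-Waugh identity on condition means", {
  tab <- linear_dmama_table(bs = 3, bi = 0.4, bint = -0.1, noise_sd = 2, seed = 31)
  fit <- fit_subject_independent(tab, "stiffness", stratum = "down_ramp")
  sub <- tab[tab$mode == "down_ramp", ]
  means <- aggregate(dmama_pct_foot ~ subject + stiffness_code, sub, mean)
  # demean response and driver within subject, then slope through the origin
  y_d <- with(means, dmama_pct_foot - ave(dmama_pct_foot, subject))
  x_d <- with(means, stiffness_code - ave(stiffness_code, subject))
  expect_equal(fit$slope, sum(x_d * y_d) / sum(x_d^2), tolerance = 1e-10)
})

test_that("incline fits use degrees and exclude stairs", {
  tab <- linear_dmama_table(bs = 0, bi = 0.45, noise_sd = 0)
  stairs <- data.frame(
    subject = 1, stiffness_code = 1, incline_deg = NA, rep = 1,
    mode = "up_stairs", dmama_pct_foot = 99
  )
  fit <- suppressWarnings(fit_subject_independent(rbind(tab, stairs), "incline", stratum = 1))
  expect_equal(fit$slope, 0.45, tolerance = 1e-10)
})

test_that("per-subject fits match the closed-form least-squares oracle", {
  tab <- linear_dmama_table(noise_sd = 2, seed = 33)
  sub <- tab[tab$subject == 2 & tab$mode == "level", ]
  fit <- fit_subject_dependent(sub, "stiffness")
  X <- cbind(1, sub$stiffness_code)
  beta <- solve(crossprod(X), crossprod(X, sub$dmama_pct_foot))
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$intercepts, beta[1], tolerance = 1e-10)
  expect_error(fit_subject_dependent(sub[1:2, ], "stiffness"), "3 strides")
})

test_that("under a zero slope the p-value is roughly uniform", {
  set.seed(35)
  pvals <- replicate(200, {
    tab <- linear_dmama_table(
      subjects = 1, codes = 0:2, inclines = 0, n_per = 10,
      bs = 0, bi = 0, noise_sd = 3, seed = sample.int(1e6, 1)
    )
    fit_subject_dependent(tab, "stiffness")$p_value
  })
  # coarse uniformity: the rejection rate at alpha = 0.05 is near nominal
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("cross-fit R^2 behaves as 1 - RSS/TSS with possible negatives", {
  tab <- linear_dmama_table(noise_sd = 2, seed = 37)
  fit <- fit_subject_independent(tab, "stiffness", stratum = "level")
  sub <- tab[tab$subject == 1 & tab$mode == "level", ]

  # predicted == adjusted: R^2 = 1 (construct a perfectly explained subject)
  perfect <- sub
  grand <- mean(fit$intercepts)
  offset <- fit$intercepts[["1"]] - grand
  perfect$dmama_pct_foot <- grand + fit$slope * perfect$stiffness_code + offset
  expect_equal(crossfit_r2(perfect, fit, subject = 1)$r_squared, 1, tolerance = 1e-10)

  # predicted == subject mean: R^2 = 0 (flat model, balanced design)
  flat_fit <- fit
  flat_fit$slope <- 0
  flat <- sub
  # residuals sum to zero so the subject mean equals the flat prediction
  flat$dmama_pct_foot <- offset + grand + c(-1, 0, 1)[1 + flat$stiffness_code]
  r0 <- crossfit_r2(flat, flat_fit, subject = 1)
  expect_equal(r0$r_squared, 0, tolerance = 1e-10)

  # counter-sloped prediction: R^2 < 0
  anti_fit <- fit
  anti_fit$slope <- -fit$slope
  counter <- perfect
  expect_lt(crossfit_r2(counter, anti_fit, subject = 1)$r_squared, 0)

  # constant subject data: undefined, flagged
  cons <- sub
  cons$dmama_pct_foot <- offset + grand
  flat2 <- flat_fit
  expect_warning(out <- crossfit_r2(cons, flat2, subject = 1), "undefined")
  expect_true(is.na(out$r_squared))
})

test_that("own-fit R^2 is never beaten by the cross-fit R^2", {
  tab <- linear_dmama_table(noise_sd = 3, seed = 39)
  fit <- fit_subject_independent(tab, "stiffness", stratum = "level")
  for (s in 1:4) {
    sub <- tab[tab$subject == s & tab$mode == "level", ]
    own <- fit_subject_dependent(sub, "stiffness")$r_squared
    cross <- crossfit_r2(sub, fit, subject = s)$r_squared
    expect_lte(cross, own + 1e-10)
  }
})

test_that("the interaction fit matches a pseudoinverse oracle", {
  tab <- linear_dmama_table(bs = 3.01, bi = 0.413, bint = -0.145, noise_sd = 1, seed = 41)
  fit <- fit_interaction(tab)
  X <- with(tab, cbind(1, stiffness_code, incline_deg, stiffness_code * incline_deg))
  beta <- pracma::pinv(X) %*% tab$dmama_pct_foot
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_true(all(fit$ci_half_width >= 0))
})

test_that("a null interaction coefficient is covered by its CI", {
  tab <- linear_dmama_table(bs = 3, bi = 0.4, bint = 0, noise_sd = 1, seed = 43)
  fit <- fit_interaction(tab)
  expect_lt(abs(fit$coefficients[["interaction"]]), fit$ci_half_width[["interaction"]])
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- linear_dmama_table(codes = 1, noise_sd = 0)
  expect_error(fit_interaction(tab), "must vary")
  one_level <- linear_dmama_table(inclines = 0, noise_sd = 0)
  expect_error(fit_subject_independent(one_level, "incline", stratum = 1), "2 driver levels")
})

test_that("subjects seen at one driver level contribute to intercepts only, with a warning", {
  tab <- linear_dmama_table(bs = 2, bi = 0, noise_sd = 0)
  solo <- tab$subject == 4 & tab$stiffness_code != 1
  tab <- tab[!solo, ]
  w <- capture_warnings(
    fit <- fit_subject_independent(tab, "stiffness", stratum = "level")
  )
  expect_match(w, "single driver level", all = FALSE)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
})

test_that("the stride-level random-intercept variant agrees on the slope", {
  skip_if_not_installed("lmerTest")
  tab <- linear_dmama_table(bs = 3, bi = 0, noise_sd = 2, seed = 45)
  m1 <- fit_subject_independent(tab, "stiffness", stratum = "level", method = "means")
  m2 <- fit_subject_independent(tab, "stiffness", stratum = "level", method = "strides")
  expect_equal(m1$slope, m2$slope, tolerance = 0.05)
  expect_lt(m2$p_value, 0.05)
})
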
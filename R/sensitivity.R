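## Sensitivity analysis: how DMAMA responds to prosthesis forefoot stiffness
## and to ground incline. Subject-independent fits pool condition means with
## per-subject intercepts (the fixed-effect slope of a mixed model, computed
## as described: a regression on subject-by-condition means with
## subject-dependent intercepts); per-subject fits run on stride-level data;
## a cross-fit R^2 measures how well the pooled trend explains one subject's
## strides; and a multiple regression captures the stiffness x incline
## interaction.

driver_values <- function(table, driver = c("stiffness", "incline")) {
  driver <- match.arg(driver)
  if (driver == "stiffness") {
    table$stiffness_code
  } else {
    table$incline_deg
  }
}

# keep analyzable rows; incline fits drop stairs (no incline is defined there)
sensitivity_rows <- function(table, driver) {
  keep <- rep(TRUE, nrow(table))
  if ("excluded" %in% names(table)) keep <- keep & !table$excluded
  if ("valid" %in% names(table)) keep <- keep & table$valid
  if (driver == "incline") {
    keep <- keep & !grepl("stairs", table$mode) & is.finite(table$incline_deg)
  }
  table[keep, , drop = FALSE]
}

#' Subject-independent sensitivity of DMAMA to a driver
#'
#' Implements the pooled analysis: within one stratum (a locomotion mode for
#' the stiffness driver, or a stiffness setting for the incline driver),
#' per-subject condition means are computed, then a least-squares fit with a
#' common slope and one intercept per subject. The slope is the
#' subject-independent sensitivity (percent foot length per stiffness
#' increment or per degree incline); the Wald p-value tests it against zero at
#' alpha = 0.05; R^2 is reported on the condition means.
#'
#' A subject observed at a single driver level contributes to its intercept
#' only (with a warning). Stair modes carry no incline and are excluded from
#' incline fits.
#'
#' @param table per-stride DMAMA table with columns `subject`,
#'   `dmama_pct_foot`, `mode`, `stiffness_code`, `incline_deg` (and optional
#'   `excluded`/`valid` flags, honored).
#' @param driver `"stiffness"` or `"incline"`.
#' @param stratum mode name (stiffness driver) or stiffness code (incline
#'   driver); `NULL` pools the whole table.
#' @param method `"means"` (default, the described computation) or
#'   `"strides"` for a stride-level random-intercept model via `lmerTest`
#'   (if installed).
#' @return object of class `sensitivity_fit`.
#' @export
fit_subject_independent <- function(table, driver = c("stiffness", "incline"),
                                    stratum = NULL,
                                    method = c("means", "strides")) {
  driver <- match.arg(driver)
  method <- match.arg(method)
  tab <- sensitivity_rows(table, driver)
  if (!is.null(stratum)) {
    tab <- if (driver == "stiffness") {
      tab[tab$mode == stratum, , drop = FALSE]
    } else {
      tab[tab$stiffness_code == stratum, , drop = FALSE]
    }
  }
  tab$x <- driver_values(tab, driver)
  if (length(unique(tab$x)) < 2) stop("need >= 2 driver levels")
  if (length(unique(tab$subject)) < 2) stop("need >= 2 subjects")
  single <- tapply(tab$x, tab$subject, function(v) length(unique(v)) < 2)
  if (any(single)) {
    warning(sprintf(
      "subject(s) %s observed at a single driver level; intercept-only contribution",
      paste(names(single)[single], collapse = ", ")
    ))
  }

  if (method == "strides") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("method = 'strides' requires the lmerTest package")
    }
    fit <- lmerTest::lmer(dmama_pct_foot ~ x + (1 | subject), data = tab)
    sm <- summary(fit)$coefficients
    slope <- sm["x", "Estimate"]
    p <- sm["x", "Pr(>|t|)"]
    r2 <- stats::cor(stats::fitted(fit), tab$dmama_pct_foot)^2
    intercepts <- sm["(Intercept)", "Estimate"] +
      stats::setNames(lme4::ranef(fit)$subject[, 1], rownames(lme4::ranef(fit)$subject))
    n <- nrow(tab)
  } else {
    means <- stats::aggregate(
      dmama_pct_foot ~ subject + x,
      data = tab, FUN = mean
    )
    means$subject <- factor(means$subject)
    fit <- stats::lm(dmama_pct_foot ~ subject + x, data = means)
    sm <- summary(fit)
    slope <- stats::coef(fit)[["x"]]
    p <- sm$coefficients["x", "Pr(>|t|)"]
    r2 <- sm$r.squared
    co <- stats::coef(fit)
    subj_levels <- levels(means$subject)
    offsets <- c(0, co[paste0("subject", subj_levels[-1])])
    intercepts <- stats::setNames(co[["(Intercept)"]] + offsets, subj_levels)
    n <- nrow(means)
  }
  structure(
    list(
      driver = driver, stratum = stratum, scope = "subject_independent",
      method = method, slope = slope, p_value = p, r_squared = r2,
      intercepts = intercepts, n = n, fit = fit
    ),
    class = "sensitivity_fit"
  )
}

#' Per-subject sensitivity of DMAMA to a driver
#'
#' Ordinary least squares on one subject's stride-level DMAMA values against
#' the driver: slope, Wald p-value, R^2.
#'
#' @param table per-stride DMAMA table for a single subject (or with a
#'   `subject` column and `subject` argument given).
#' @param driver `"stiffness"` or `"incline"`.
#' @param stratum optional stratum as in [fit_subject_independent()].
#' @param subject optional subject id to filter on.
#' @return object of class `sensitivity_fit` with scope
#'   `"subject_dependent"`.
#' @export
fit_subject_dependent <- function(table, driver = c("stiffness", "incline"),
                                  stratum = NULL, subject = NULL) {
  driver <- match.arg(driver)
  tab <- sensitivity_rows(table, driver)
  if (!is.null(subject)) tab <- tab[tab$subject == subject, , drop = FALSE]
  if (!is.null(stratum)) {
    tab <- if (driver == "stiffness") {
      tab[tab$mode == stratum, , drop = FALSE]
    } else {
      tab[tab$stiffness_code == stratum, , drop = FALSE]
    }
  }
  if (nrow(tab) < 3) stop("need at least 3 strides")
  tab$x <- driver_values(tab, driver)
  if (length(unique(tab$x)) < 2) stop("need >= 2 driver levels")
  fit <- stats::lm(dmama_pct_foot ~ x, data = tab)
  sm <- summary(fit)
  structure(
    list(
      driver = driver, stratum = stratum, scope = "subject_dependent",
      subject = subject %||% unique(tab$subject)[1],
      slope = stats::coef(fit)[["x"]],
      p_value = sm$coefficients["x", "Pr(>|t|)"],
      r_squared = sm$r.squared,
      intercepts = stats::coef(fit)[["(Intercept)"]],
      n = nrow(tab), fit = fit
    ),
    class = "sensitivity_fit"
  )
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_fit> %s, driver %s%s: slope %.3f %%FL/unit, p = %.3g, R^2 = %.3f (n = %d)\n",
    x$scope, x$driver,
    if (!is.null(x$stratum)) paste0(", stratum ", x$stratum) else "",
    x$slope, x$p_value, x$r_squared, x$n
  ))
  invisible(x)
}

#' Cross-fit R-squared of the pooled trend on one subject's strides
#'
#' Measures how well the subject-independent best-fit line explains a single
#' subject's stride-by-stride DMAMA: `R^2 = 1 - RSS/TSS`, where the residuals
#' compare each stride's random-effect-adjusted DMAMA with the pooled-model
#' prediction, and TSS is taken about the subject's mean adjusted value.
#' Values can be negative when the pooled trend fits worse than the subject's
#' own mean. The adjustment subtracts the subject's fitted intercept offset
#' relative to the grand (mean) intercept.
#'
#' @param table per-stride DMAMA table for one subject.
#' @param fit a subject-independent `sensitivity_fit`.
#' @param subject subject id (needed to pick the intercept; defaults to the
#'   table's single subject).
#' @return list with `r_squared` (may be negative; `NA` with a warning when
#'   the subject's adjusted values are constant), `rss`, `tss`, `n`.
#' @export
crossfit_r2 <- function(table, fit, subject = NULL) {
  stopifnot(inherits(fit, "sensitivity_fit"))
  tab <- sensitivity_rows(table, fit$driver)
  if (!is.null(fit$stratum)) {
    tab <- if (fit$driver == "stiffness") {
      tab[tab$mode == fit$stratum, , drop = FALSE]
    } else {
      tab[tab$stiffness_code == fit$stratum, , drop = FALSE]
    }
  }
  if (is.null(subject)) subject <- unique(tab$subject)[1]
  tab <- tab[tab$subject == subject, , drop = FALSE]
  if (!nrow(tab)) stop("no strides for this subject")
  x <- driver_values(tab, fit$driver)
  grand <- mean(fit$intercepts)
  offset <- fit$intercepts[[as.character(subject)]] - grand
  adjusted <- tab$dmama_pct_foot - offset
  predicted <- grand + fit$slope * x
  rss <- sum((adjusted - predicted)^2)
  tss <- sum((adjusted - mean(adjusted))^2)
  if (tss == 0) {
    warning("constant adjusted DMAMA for this subject; cross-fit R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - rss / tss
  }
  list(r_squared = r2, rss = rss, tss = tss, n = nrow(tab))
}

#' Stiffness x incline interaction regression
#'
#' Multiple linear regression of stride-level DMAMA on stiffness code, ground
#' incline, and their product, over the three ground-incline conditions only
#' (stairs are excluded — they have no incline). Reports each coefficient with
#' its classical t-based 95 percent confidence half-width.
#'
#' @param table per-stride DMAMA table.
#' @return object of class `interaction_fit`: `coefficients` (intercept,
#'   stiffness, incline, interaction), `ci_half_width`, `n`, underlying `fit`.
#' @export
fit_interaction <- function(table) {
  tab <- sensitivity_rows(table, "incline")
  if (length(unique(tab$stiffness_code)) < 2 ||
      length(unique(tab$incline_deg)) < 2) {
    stop("both stiffness and incline must vary")
  }
  fit <- stats::lm(dmama_pct_foot ~ stiffness_code * incline_deg, data = tab)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design: term(s) %s collapsed", paste(bad, collapse = ", ")))
  }
  ci <- stats::confint(fit, level = 0.95)
  co <- stats::coef(fit)
  nm <- c("intercept", "stiffness", "incline", "interaction")
  structure(
    list(
      coefficients = stats::setNames(as.numeric(co), nm),
      ci_half_width = stats::setNames(as.numeric((ci[, 2] - ci[, 1]) / 2), nm),
      n = nrow(tab),
      fit = fit
    ),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> n = %d strides\n", x$n))
  for (nm in names(x$coefficients)) {
    cat(sprintf(
      "  %-11s %7.3f +/- %.3f\n", nm, x$coefficients[[nm]], x$ci_half_width[[nm]]
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
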
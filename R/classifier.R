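## Locomotion-mode classification from load-cell-derived channels only:
## pre-toe-off windowing, 54-feature extraction (9 channels x 6 statistics),
## greedy forward selection, window-length optimization, and pooled-covariance
## LDA with stratified k-fold cross-validation per (subject, stiffness) group.

classifier_channel_names <- function() {
  c("fx", "fy", "fz", "mx", "my", "mz", "ankle_moment", "knee_moment", "f_sagittal")
}

feature_stat_names <- function() c("mean", "sd", "min", "max", "start", "end")

#' Derived classifier channels from a shank-frame wrench series
#'
#' Builds the nine sensor channels the classifier consumes: the six load-cell
#' axes, the transported ankle and knee sagittal moments, and the sagittal
#' force magnitude.
#'
#' @param series a `wrench_series` in the shank frame (typically resampled to
#'   100 Hz first).
#' @param geometry a `subject_geometry`.
#' @return data.frame: `time` plus the nine channels.
#' @export
classifier_channels <- function(series, geometry) {
  jm <- joint_moments(series, geometry)
  data.frame(
    time = series$time,
    fx = series$force[, 1], fy = series$force[, 2], fz = series$force[, 3],
    mx = series$moment[, 1], my = series$moment[, 2], mz = series$moment[, 3],
    ankle_moment = jm$ankle_moment,
    knee_moment = jm$knee_moment,
    f_sagittal = sqrt(series$force[, 1]^2 + series$force[, 2]^2)
  )
}

#' Extract the pre-toe-off data window
#'
#' Returns the samples in `[toe_off - window_ms, toe_off]`, inclusive of the
#' toe-off sample. The window ends at toe-off because toe-off is easily
#' detectable from the load cell and the window then carries stance
#' information available before a swing-phase stiffness decision.
#'
#' @param channels data.frame with a `time` column (uniformly resampled).
#' @param toe_off_time toe-off time, s.
#' @param window_ms window length, ms.
#' @return data.frame of in-window samples, or `NULL` (with a warning) when
#'   the window would extend before the series start.
#' @export
extract_window <- function(channels, toe_off_time, window_ms = 300) {
  t_start <- toe_off_time - window_ms / 1000
  eps <- 1e-9
  if (t_start < channels$time[1] - eps) {
    warning("window extends before the series start; stride dropped")
    return(NULL)
  }
  channels[channels$time >= t_start - eps & channels$time <= toe_off_time + eps, ,
    drop = FALSE
  ]
}

#' Extract the 54-feature vector from one window
#'
#' Six statistics (mean, sample SD, min, max, starting value, ending value)
#' for each of the nine channels, in fixed channel-major order. A
#' single-sample window has SD 0 by definition.
#'
#' @param window data.frame from [extract_window()] (a `time` column, if
#'   present, is ignored).
#' @return named numeric vector of length 54 (`<channel>_<stat>`).
#' @export
extract_features <- function(window) {
  if (is.null(window) || nrow(window) == 0) stop("window is empty")
  chans <- setdiff(names(window), "time")
  out <- unlist(lapply(chans, function(ch) {
    x <- window[[ch]]
    s <- if (length(x) > 1) stats::sd(x) else 0
    v <- c(mean(x), s, min(x), max(x), x[1], x[length(x)])
    names(v) <- paste(ch, feature_stat_names(), sep = "_")
    v
  }))
  out
}

feature_columns <- function(table) {
  setdiff(
    names(table),
    c("subject", "stiffness", "stiffness_code", "mode", "stride_id")
  )
}

#' Build the stride feature table for a synthetic session
#'
#' Runs the classifier path end to end for every trial of a gait session:
#' rotate into the shank frame, resample uniformly, derive the nine channels,
#' detect events, segment strides (dropping transition-excluded ones), window
#' each stride before its toe-off, and extract the 54 features.
#'
#' @param session a `gait_session`.
#' @param geometries list of `subject_geometry` per subject (calibrated or
#'   true); defaults to the session's true geometry.
#' @param window_ms window length, ms.
#' @param rate resampling rate, Hz.
#' @return data.frame: `subject`, `stiffness_code`, `mode`, plus 54 feature
#'   columns; one row per included stride.
#' @export
build_feature_table <- function(session, geometries = session$geometry,
                                window_ms = 300, rate = 100) {
  prep <- prepare_classifier_trials(session, geometries, rate)
  feature_table_from_prep(prep, window_ms)
}

# cacheable per-trial preprocessing so window optimization does not redo
# rotation/resampling/segmentation per candidate window
prepare_classifier_trials <- function(session, geometries = session$geometry,
                                      rate = 100) {
  lapply(session$trials, function(tr) {
    geom <- geometries[[tr$subject]]
    shank <- to_shank_frame(tr$series, geom)
    uni <- resample_uniform(shank, rate)
    ch <- classifier_channels(uni, geom)
    ev <- detect_events(shank, geom$body_weight)
    seg <- segment_strides(ev, tr$labels, stiffness_code = tr$stiffness_code)
    list(
      subject = tr$subject, stiffness_code = tr$stiffness_code,
      channels = ch, segments = seg[!seg$excluded, , drop = FALSE]
    )
  })
}

feature_table_from_prep <- function(prep, window_ms) {
  rows <- list()
  for (tr in prep) {
    seg <- tr$segments
    for (i in seq_len(nrow(seg))) {
      w <- extract_window(tr$channels, seg$toe_off[i], window_ms)
      if (is.null(w)) next
      rows[[length(rows) + 1]] <- c(
        list(
          subject = tr$subject, stiffness_code = tr$stiffness_code,
          mode = seg$mode[i]
        ),
        as.list(extract_features(w))
      )
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

## ---- LDA with pooled covariance and diagonal shrinkage ----

# pooled within-class covariance blended toward its diagonal:
# S(lambda) = (1 - lambda) S + lambda diag(S). lambda escalates automatically
# through `ladder` if the blended matrix is not positive definite.
lda_train <- function(X, y, lambda = 0) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least two classes")
  n <- nrow(X)
  p <- ncol(X)
  mm <- vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]), numeric(p))
  means <- if (p == 1) matrix(mm, ncol = 1) else t(mm) # K x p
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    if (nrow(Xc) > 1) {
      S <- S + crossprod(scale(Xc, center = TRUE, scale = FALSE))
    }
  }
  S <- S / max(1, n - length(classes))
  ladder <- unique(pmax(lambda, c(lambda, 0.01, 0.1, 0.5, 1)))
  Sinv <- NULL
  used <- NA_real_
  for (l in ladder) {
    Sl <- (1 - l) * S + l * diag(diag(S), p)
    ch <- tryCatch(chol(Sl), error = function(e) NULL)
    if (!is.null(ch)) {
      Sinv <- chol2inv(ch)
      used <- l
      break
    }
  }
  if (is.null(Sinv)) { # fully degenerate diagonal (constant features): ridge
    Sl <- diag(diag(S) + 1e-8 * mean(diag(S) + 1e-12), p)
    Sinv <- solve(Sl)
    used <- 1
  }
  W <- Sinv %*% t(means) # p x K
  b <- -0.5 * colSums(t(means) * W) + log(as.numeric(table(y)[classes]) / n)
  list(classes = classes, W = W, b = b, lambda = used)
}

lda_predict <- function(model, X) {
  scores <- as.matrix(X) %*% model$W + rep(model$b, each = nrow(X))
  factor(model$classes[max.col(scores, ties.method = "first")],
    levels = model$classes
  )
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds
make_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# cross-validated predictions per (subject, stiffness) group; returns a
# data.frame of true/predicted labels over all held-out strides
cv_predictions <- function(table, features, folds = 10, seed = 1, lambda = 0) {
  modes_present <- intersect(locomotion_modes(), unique(table$mode))
  if (length(modes_present) < 2) stop("need at least two classes")
  if (length(features) < 1) stop("need at least one feature")
  grp <- if (all(c("subject", "stiffness_code") %in% names(table))) {
    interaction(table$subject, table$stiffness_code, drop = TRUE)
  } else {
    factor(rep(1, nrow(table)))
  }
  truth <- pred <- character(0)
  for (g in levels(grp)) {
    sub <- table[grp == g, , drop = FALSE]
    y <- factor(sub$mode, levels = modes_present)
    min_class <- min(table(droplevels(y)))
    k <- min(folds, min_class)
    if (k < folds) {
      warning(sprintf(
        "group %s: smallest class has %d members; using %d folds", g, min_class, k
      ))
    }
    if (k < 2) stop(sprintf("group %s: a class has < 2 members, cannot cross-validate", g))
    fold <- make_folds(as.character(y), k, seed)
    X <- as.matrix(sub[, features, drop = FALSE])
    for (f in seq_len(k)) {
      train <- fold != f
      model <- lda_train(X[train, , drop = FALSE], y[train], lambda = lambda)
      yhat <- lda_predict(model, X[!train, , drop = FALSE])
      truth <- c(truth, as.character(y[!train]))
      pred <- c(pred, as.character(yhat))
    }
  }
  data.frame(truth = truth, pred = pred, stringsAsFactors = FALSE)
}

cv_error <- function(table, features, folds = 10, seed = 1, lambda = 0) {
  cp <- cv_predictions(table, features, folds = folds, seed = seed, lambda = lambda)
  mean(cp$truth != cp$pred)
}

#' Greedy forward feature selection
#'
#' Sequentially adds the feature whose inclusion minimizes the mean
#' cross-validated misclassification error (stratified k-fold within each
#' (subject, stiffness) group), stopping when no candidate strictly reduces
#' the error. Ties are broken by the lowest feature column index, and the fold
#' assignment is seeded, so the selection is deterministic.
#'
#' @param table feature table from [build_feature_table()] (label column
#'   `mode`; grouping columns `subject`, `stiffness_code` when present).
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param lambda LDA shrinkage parameter (see [train_eval_lda()]).
#' @param max_features optional cap on the number of selected features.
#' @return list with `features` (selected names, in selection order) and
#'   `error_trace` (CV error after each accepted feature).
#' @export
forward_select <- function(table, folds = 10, seed = 1, lambda = 0,
                           max_features = Inf) {
  all_feats <- feature_columns(table)
  if (length(unique(table$mode)) < 2) stop("need at least two classes")
  selected <- character(0)
  best_err <- Inf
  trace <- numeric(0)
  repeat {
    if (length(selected) >= max_features) break
    cand <- setdiff(all_feats, selected)
    if (!length(cand)) break
    errs <- vapply(cand, function(f) {
      suppressWarnings(
        cv_error(table, c(selected, f), folds = folds, seed = seed, lambda = lambda)
      )
    }, numeric(1))
    i <- which.min(errs) # ties: lowest column index (cand preserves order)
    if (errs[i] < best_err) {
      selected <- c(selected, cand[i])
      best_err <- errs[i]
      trace <- c(trace, best_err)
    } else {
      break
    }
  }
  list(features = selected, error_trace = trace)
}

#' Optimize the pre-toe-off window length
#'
#' Rebuilds the feature table at each candidate window length and returns the
#' one minimizing the cross-validated misclassification error of the
#' reduced-feature model. Ties go to the smallest window. The default grid is
#' 100-500 ms in 33 ms increments (100, 133, ..., 496 ms).
#'
#' @param builder function taking a window length (ms) and returning a feature
#'   table, e.g. `function(w) build_feature_table(session, window_ms = w)`.
#' @param candidates candidate window lengths, ms.
#' @param features feature subset to evaluate (`NULL` = all).
#' @param folds,seed,lambda passed to the CV evaluation.
#' @return list with `window_ms` (best), `errors` (named per candidate).
#' @export
optimize_window <- function(builder, candidates = seq(100, 500, by = 33),
                            features = NULL, folds = 10, seed = 1, lambda = 0) {
  if (!length(candidates)) stop("candidate list is empty")
  candidates <- sort(candidates)
  errs <- vapply(candidates, function(w) {
    tab <- builder(w)
    f <- if (is.null(features)) feature_columns(tab) else features
    suppressWarnings(cv_error(tab, f, folds = folds, seed = seed, lambda = lambda))
  }, numeric(1))
  names(errs) <- candidates
  list(window_ms = candidates[which.min(errs)], errors = errs)
}

#' Train and evaluate the LDA locomotion-mode classifier
#'
#' Pooled-covariance linear discriminant analysis fitted per (subject,
#' stiffness) group — stiffness is known to a real-time controller, so models
#' are conditioned on it — evaluated by stratified k-fold cross-validation and
#' aggregated into a single confusion matrix. Class imbalance is retained (no
#' resampling); priors follow the training proportions. When a group's pooled
#' covariance is singular, diagonal shrinkage is escalated automatically;
#' `lambda` sets the starting blend.
#'
#' @param table feature table (label `mode`; groups `subject`,
#'   `stiffness_code` when present).
#' @param features feature subset (`NULL` = all columns).
#' @param folds number of CV folds (reduced per group, with a warning, when a
#'   class has fewer members).
#' @param seed integer seed for the stratified fold assignment.
#' @param lambda initial shrinkage in `[0, 1]` blending the pooled covariance
#'   toward its diagonal.
#' @return object of class `classifier_report`: `confusion` (true x
#'   predicted), `per_class_accuracy` (%), `overall_accuracy` (%),
#'   `features`, `folds`, `seed`.
#' @export
train_eval_lda <- function(table, features = NULL, folds = 10, seed = 1,
                           lambda = 0) {
  if (is.null(features)) features <- feature_columns(table)
  cp <- cv_predictions(table, features, folds = folds, seed = seed, lambda = lambda)
  modes_present <- intersect(locomotion_modes(), unique(cp$truth))
  confusion <- table(
    factor(cp$truth, levels = modes_present),
    factor(cp$pred, levels = modes_present),
    dnn = c("true", "predicted")
  )
  per_class <- 100 * diag(confusion) / pmax(1, rowSums(confusion))
  structure(
    list(
      confusion = confusion,
      per_class_accuracy = per_class,
      overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
      features = features,
      folds = folds,
      seed = seed
    ),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> overall accuracy %.2f%% (%d strides, %d features, %d-fold CV)\n",
    x$overall_accuracy, sum(x$confusion), length(x$features), x$folds
  ))
  print(x$confusion)
  cat("per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}
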
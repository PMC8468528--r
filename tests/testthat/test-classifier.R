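# Locomotion-mode classifier: windowing, features, forward selection,
# window optimization, and cross-validated LDA.

# feature table with K Gaussian classes: `informative` features separate the
# classes by `sep` SDs, the rest are pure noise
gaussian_table <- function(n_per = 30, classes = c("level", "up_ramp"),
                           p = 8, informative = 1, sep = 6, seed = 1) {
  set.seed(seed)
  n <- n_per * length(classes)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(classes, each = n_per)
  for (j in seq_len(informative)) {
    X[, j] <- X[, j] + sep * (as.integer(factor(y, levels = classes)) - 1)
  }
  tab <- as.data.frame(X)
  names(tab) <- paste0("f", seq_len(p))
  tab$mode <- y
  tab
}

test_that("a 300 ms window at 100 Hz holds 31 samples, endpoints inclusive", {
  ch <- data.frame(time = seq(0, 2, by = 0.01), fy = 1)
  w <- extract_window(ch, toe_off_time = 1.5, window_ms = 300)
  expect_identical(nrow(w), 31L)
  expect_equal(w$time[1], 1.2)
  expect_equal(w$time[nrow(w)], 1.5)
  # a window spanning the full series starts at the first sample
  w2 <- extract_window(ch, toe_off_time = 2, window_ms = 2000)
  expect_equal(w2$time[1], 0)
  # equal window length => equal sample count across strides
  w3 <- extract_window(ch, toe_off_time = 0.8, window_ms = 300)
  expect_identical(nrow(w3), nrow(w))
  # window before the series start: stride dropped with a warning
  expect_warning(out <- extract_window(ch, toe_off_time = 0.1, window_ms = 300), "dropped")
  expect_null(out)
})

test_that("feature extraction computes the six statistics per channel", {
  w <- data.frame(time = 1:3, a = c(1, 2, 3), b = c(5, 5, 5))
  f <- extract_features(w)
  expect_equal(unname(f[c("a_mean", "a_sd", "a_min", "a_max", "a_start", "a_end")]),
    c(2, 1, 1, 3, 1, 3))
  expect_equal(unname(f[c("b_mean", "b_sd", "b_min", "b_max", "b_start", "b_end")]),
    c(5, 0, 5, 5, 5, 5))
  # single-sample window: SD defined as 0
  f1 <- extract_features(data.frame(a = 4))
  expect_equal(unname(f1["a_sd"]), 0)
  expect_error(extract_features(data.frame()), "empty")
})

test_that("nine channels yield exactly 54 features, invariant to time position", {
  set.seed(3)
  vals <- matrix(rnorm(9 * 20), 20, 9)
  w <- as.data.frame(cbind(seq(0, 0.19, by = 0.01), vals))
  names(w) <- c("time", dmama:::classifier_channel_names())
  f <- extract_features(w)
  expect_identical(length(f), 54L)
  w_shift <- w
  w_shift$time <- w$time + 100
  expect_identical(f, extract_features(w_shift))
})

test_that("forward selection finds the separating feature first", {
  tab <- gaussian_table(n_per = 40, p = 12, informative = 1, sep = 8, seed = 5)
  sel <- forward_select(tab, folds = 5, seed = 1)
  expect_identical(sel$features[1], "f1")
  # oracle: exhaustive single-feature search agrees on the first pick
  errs <- vapply(paste0("f", 1:12), function(f) {
    dmama:::cv_error(tab, f, folds = 5, seed = 1)
  }, numeric(1))
  expect_identical(sel$features[1], names(which.min(errs)))
  # the accepted error trace never increases
  expect_true(all(diff(sel$error_trace) <= 0))
  expect_gt(length(sel$features), 0)
})

test_that("identical feature copies select exactly one, by lowest column index", {
  tab <- gaussian_table(n_per = 30, p = 1, informative = 1, sep = 8, seed = 7)
  tab <- data.frame(f1 = tab$f1, f2 = tab$f1, f3 = tab$f1, mode = tab$mode)
  sel <- forward_select(tab, folds = 5, seed = 2)
  expect_identical(sel$features, "f1")
})

test_that("forward selection rejects single-class input", {
  tab <- gaussian_table(n_per = 10)
  tab$mode <- "level"
  expect_error(forward_select(tab, folds = 2, seed = 1), "two classes")
})

test_that("the window grid is 100-500 ms in 33 ms steps (13 candidates)", {
  grid <- eval(formals(optimize_window)$candidates)
  expect_identical(length(grid), 13L)
  expect_identical(grid[1], 100)
  expect_identical(grid[13], 496)
  expect_true(all(diff(grid) == 33))
})

test_that("window optimization minimizes CV error with ties to the smallest window", {
  tab <- gaussian_table(n_per = 25, p = 4, informative = 1, sep = 8, seed = 9)
  builder <- function(w) tab # window-independent table: error curve is flat
  out <- optimize_window(builder, candidates = c(300, 100, 200), folds = 5, seed = 1)
  expect_identical(out$window_ms, 100)
  out1 <- optimize_window(builder, candidates = 250, folds = 5, seed = 1)
  expect_identical(out1$window_ms, 250)
  expect_error(optimize_window(builder, candidates = numeric(0)), "empty")
})

test_that("well-separated classes reach 100% CV accuracy; bookkeeping holds", {
  tab <- gaussian_table(
    n_per = 100, classes = c("level", "up_ramp"), p = 6,
    informative = 2, sep = 8, seed = 11
  )
  rep <- train_eval_lda(tab, folds = 10, seed = 1)
  expect_equal(rep$overall_accuracy, 100)
  expect_identical(sum(rep$confusion), 200L)
  # trace / total equals the reported overall accuracy
  expect_equal(100 * sum(diag(rep$confusion)) / sum(rep$confusion), rep$overall_accuracy)
  # row sums equal per-class stride counts
  expect_equal(unname(rowSums(rep$confusion)), c(100, 100))
})

test_that("permuted labels drop accuracy to chance for five balanced classes", {
  tab <- gaussian_table(
    n_per = 60, classes = locomotion_modes(), p = 10,
    informative = 4, sep = 6, seed = 13
  )
  set.seed(99)
  tab$mode <- sample(tab$mode)
  rep <- train_eval_lda(tab, folds = 10, seed = 1)
  n <- sum(rep$confusion)
  half <- 100 * 2.576 * sqrt(0.2 * 0.8 / n)
  expect_gt(rep$overall_accuracy, 20 - half - 2) # small LDA null bias allowed
  expect_lt(rep$overall_accuracy, 20 + half + 2)
})

test_that("the selection-evaluation chain is reproducible under a fixed seed", {
  tab <- gaussian_table(n_per = 30, p = 6, informative = 2, sep = 3, seed = 15)
  a <- train_eval_lda(tab, folds = 5, seed = 42)
  b <- train_eval_lda(tab, folds = 5, seed = 42)
  expect_identical(a$confusion, b$confusion)
  sa <- forward_select(tab, folds = 5, seed = 42)
  sb <- forward_select(tab, folds = 5, seed = 42)
  expect_identical(sa, sb)
})

test_that("the pooled-covariance LDA agrees with an established implementation", {
  skip_if_not_installed("MASS")
  tab <- gaussian_table(
    n_per = 50, classes = c("level", "up_ramp", "down_ramp"), p = 5,
    informative = 2, sep = 2.5, seed = 17
  )
  X <- as.matrix(tab[, paste0("f", 1:5)])
  y <- factor(tab$mode)
  model <- dmama:::lda_train(X, y, lambda = 0)
  mine <- dmama:::lda_predict(model, X)
  ref <- predict(MASS::lda(X, grouping = y))$class
  expect_gt(mean(as.character(mine) == as.character(ref)), 0.99)
})

test_that("groups with small classes reduce their fold count with a warning", {
  tab <- gaussian_table(n_per = 5, classes = c("level", "up_ramp"), p = 3,
    informative = 1, sep = 8, seed = 19)
  expect_warning(train_eval_lda(tab, folds = 10, seed = 1), "folds")
})

test_that("the session-level feature table carries labels and 54 features", {
  cfg <- tiny_config(seed = 23)
  ses <- generate_session(cfg)
  tab <- build_feature_table(ses)
  expect_identical(length(dmama:::feature_columns(tab)), 54L)
  expect_true(all(tab$mode %in% locomotion_modes()))
  # transition strides were dropped before feature extraction
  expect_identical(
    nrow(tab),
    sum(!ses$truth$transition)
  )
  expect_false(anyNA(tab))
})
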
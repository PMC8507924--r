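test_that("metric panel matches hand-computed confusion cases", {
  perfect <- confusion_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                               c(0.1, 0.2, 0.8, 0.9))
  for (m in c("accuracy", "precision", "recall", "f1", "auc", "mcc"))
    expect_equal(perfect[[m]], 1.0)

  # TP=10, TN=9, FP=4, FN=6: MCC = 66 / sqrt(43680)
  y_true <- c(rep(1, 16), rep(0, 13))
  y_pred <- c(rep(1, 10), rep(0, 6), rep(1, 4), rep(0, 9))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m[["mcc"]], 66 / sqrt(43680), tolerance = 1e-12)
  expect_equal(m[["mcc"]], 0.3158, tolerance = 1e-4)
  expect_equal(m[["accuracy"]], 19 / 29)
  expect_equal(m[["precision"]], 10 / 14)
  expect_equal(m[["recall"]], 10 / 16)
  expect_equal(m[["f1"]],
               2 * (10 / 14) * (10 / 16) / (10 / 14 + 10 / 16))
  expect_equal(m[["precision_macro"]], (10 / 14 + 9 / 15) / 2)

  auc_case <- confusion_metrics(c(0, 0, 1, 1), c(0, 0, 0, 1),
                                c(0.1, 0.4, 0.35, 0.8))
  expect_equal(auc_case[["auc"]], 0.75)

  w1 <- capture_warnings(z <- confusion_metrics(c(0, 0, 1), c(0, 0, 0)))
  expect_true(any(grepl("precision", w1)))
  expect_equal(z[["precision"]], 0)
  w2 <- capture_warnings(s <- confusion_metrics(c(1, 1), c(1, 0)))
  expect_true(any(grepl("single class", w2)))
  expect_true(is.na(s[["mcc"]]))
})

test_that("AUC equals explicit pair counting with ties at one half", {
  for (s in 1:10) {
    set.seed(s)
    y <- sample(rep(0:1, 10))
    p <- round(runif(20), 1)  # coarse grid forces ties
    m <- suppressWarnings(confusion_metrics(y, as.integer(p >= 0.5), p))
    expect_equal(m[["auc"]], auc_pairs(y, p), tolerance = 1e-12)
  }
})

test_that("ROC sweep brackets (0,0) to (1,1) and integrates to the AUC", {
  sep <- roc_points(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$fpr[1], 0); expect_equal(sep$tpr[1], 0)
  expect_equal(sep$fpr[nrow(sep)], 1); expect_equal(sep$tpr[nrow(sep)], 1)
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(roc_auc_trapezoid(sep), 1.0)

  flat <- roc_points(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(nrow(flat), 2)
  expect_equal(roc_auc_trapezoid(flat), 0.5)

  for (s in 1:8) {
    set.seed(s)
    y <- sample(rep(0:1, 10))
    p <- round(runif(20), 1)
    pts <- roc_points(y, p)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(roc_auc_trapezoid(pts), auc_pairs(y, p),
                 tolerance = 1e-12)
  }
  expect_error(roc_points(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUC is invariant under strictly monotone probability maps", {
  set.seed(12)
  y <- sample(rep(0:1, 12))
  p <- runif(24)
  a1 <- mann_whitney_auc_test(y, p)
  expect_equal(mann_whitney_auc_test(y, plogis(5 * p - 2)), a1)
  expect_equal(mann_whitney_auc_test(y, p^3), a1)
})

test_that("each subject is held out exactly once per LOOCV pass", {
  tab <- toy_table(n = 16, p = 12, informative = 3)
  res <- loocv_run(tab, eval_config(rfe = FALSE,
                                    gboost = list(n_estimators = 20,
                                                  learning_rate = 0.1,
                                                  max_depth = 1,
                                                  subsample = 1,
                                                  min_leaf = 2)),
                   trial_seed = 1)
  expect_equal(nrow(res), 16)
  expect_equal(sort(res$subject), sort(tab$subject_ids))
  expect_false(anyDuplicated(res$subject) > 0)
  expect_true(all(res$y_prob > 0 & res$y_prob < 1))
})

test_that("a cohort of identical twins is memorized by deep boosting", {
  set.seed(14)
  half <- matrix(rnorm(8 * 6, sd = 3), 8, 6,
                 dimnames = list(NULL, sprintf("f%d", 1:6)))
  x <- rbind(half, half)
  y <- rep(rep(c("short", "long"), 4), 2)
  vecs <- lapply(seq_len(16), function(i) x[i, ])
  names(vecs) <- sprintf("s%02d", 1:16)
  tab <- assemble_feature_table(vecs, y)
  res <- loocv_run(tab, eval_config(rfe = FALSE,
                                    gboost = list(n_estimators = 150,
                                                  learning_rate = 0.5,
                                                  max_depth = 4,
                                                  subsample = 1,
                                                  min_leaf = 1)),
                   trial_seed = 2)
  expect_equal(mean(res$y_pred == res$y_true), 1.0)
})

test_that("single-class training folds fall back to the majority class", {
  vecs <- list(a = c(f1 = 1, f2 = 0), b = c(f1 = 2, f2 = 1),
               c = c(f1 = 3, f2 = 0))
  tab <- assemble_feature_table(vecs, c("short", "short", "long"))
  expect_warning(res <- loocv_run(tab, eval_config(rfe = FALSE),
                                  trial_seed = 1), "single-class")
  expect_equal(res$y_prob[3], 1)  # both remaining subjects are short
})

test_that("label-shuffled cohorts score at chance level", {
  tab <- toy_table(n = 24, p = 30, informative = 0, seed = 19)
  rep0 <- repeated_trials(tab, eval_config(rfe = FALSE,
                                           gboost = list(n_estimators = 30,
                                                         learning_rate = 0.1,
                                                         max_depth = 1,
                                                         subsample = 0.8,
                                                         min_leaf = 3)),
                          n_trials = 20, base_seed = 31)
  band <- 1.96 * sqrt(0.25 / 24)
  expect_lt(abs(mean(rep0$per_trial$accuracy) - 0.5), band)
  expect_gte(mean(rep0$per_trial$auc), 0.4)
  expect_lte(mean(rep0$per_trial$auc), 0.6)
})

test_that("repeated trials are deterministic and reduce to one run", {
  tab <- toy_table(n = 14, p = 10, informative = 2, seed = 23)
  cfg <- eval_config(rfe = FALSE,
                     gboost = list(n_estimators = 25, learning_rate = 0.1,
                                   max_depth = 1, subsample = 0.8,
                                   min_leaf = 2))
  r1 <- repeated_trials(tab, cfg, n_trials = 1, base_seed = 5)
  single <- loocv_run(tab, cfg, trial_seed = derive_seed_test(5, 1))
  expect_identical(r1$trials[[1]], single)
  expect_equal(unname(r1$mean["accuracy"]),
               mean(single$y_pred == single$y_true))

  r2 <- repeated_trials(tab, cfg, n_trials = 3, base_seed = 9)
  r3 <- repeated_trials(tab, cfg, n_trials = 3, base_seed = 9)
  expect_identical(r2$per_trial, r3$per_trial)
})

test_that("feature selection pays off on sparse weak high-dimensional signal", {
  tab <- toy_table(n = 28, p = 240, informative = 4, d = 1.1, seed = 27)
  cfg_gb <- list(n_estimators = 100, learning_rate = 0.1, max_depth = 2,
                 subsample = 0.8, min_leaf = 2)
  with_rfe <- repeated_trials(
    tab, eval_config(rfe = TRUE, n_select = 12, step_fraction = 0.2,
                     rfe_trees = 150, gboost = cfg_gb),
    n_trials = 10, base_seed = 3)
  without <- repeated_trials(tab, eval_config(rfe = FALSE, gboost = cfg_gb),
                             n_trials = 10, base_seed = 3)
  expect_gte(mean(with_rfe$per_trial$accuracy),
             mean(without$per_trial$accuracy))
})

test_that("leaky whole-dataset selection is flagged and still runs", {
  tab <- toy_table(n = 16, p = 30, informative = 3, seed = 29)
  cfg <- eval_config(rfe = TRUE, n_select = 5, step_fraction = 0.3,
                     rfe_trees = 60, paper_faithful = TRUE,
                     gboost = list(n_estimators = 20, learning_rate = 0.1,
                                   max_depth = 1, subsample = 1,
                                   min_leaf = 2))
  expect_warning(res <- loocv_run(tab, cfg, trial_seed = 4), "leak")
  expect_equal(nrow(res), 16)
})
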
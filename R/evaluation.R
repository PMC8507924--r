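#' Evaluation pipeline configuration
#'
#' Options for [loocv_run()] / [repeated_trials()]: whether random-forest
#' RFE runs inside each training fold (the leakage-safe default) or once on
#' the full data before cross-validation (`paper_faithful = TRUE`, which
#' logs a leakage warning), the selection size, the forest used inside RFE,
#' the gradient-boosting configuration, and optional inner-CV tuning.
#'
#' @param rfe run RF-RFE feature selection.
#' @param n_select features kept by RFE (default 60).
#' @param step_fraction RFE per-iteration removal fraction.
#' @param rfe_trees trees per RFE forest.
#' @param gboost named list of [fit_gboost()] arguments.
#' @param tune run [tune_hyperparameters()] on each training fold.
#' @param grid tuning grid (default [default_gboost_grid()]).
#' @param inner_folds folds for tuning.
#' @param paper_faithful select (and tune, if enabled) once on the full
#'   dataset before cross-validation.
#' @param pool_roc `"first"` (ROC from trial 1) or `"all"` (pooled over
#'   trials).
#' @return List of class `eval_config`.
#' @export
eval_config <- function(rfe = TRUE, n_select = 60, step_fraction = 0.1,
                        rfe_trees = 200,
                        gboost = list(n_estimators = 200,
                                      learning_rate = 0.05, max_depth = 1,
                                      subsample = 0.8, min_leaf = 5),
                        tune = FALSE, grid = NULL, inner_folds = 5,
                        paper_faithful = FALSE, pool_roc = "first") {
  structure(list(rfe = rfe, n_select = n_select,
                 step_fraction = step_fraction, rfe_trees = rfe_trees,
                 gboost = gboost, tune = tune, grid = grid,
                 inner_folds = inner_folds, paper_faithful = paper_faithful,
                 pool_roc = pool_roc),
            class = "eval_config")
}

#' Confusion-matrix metric panel
#'
#' Accuracy, precision, recall, F1 (harmonic mean), Mann-Whitney AUC (ties
#' counted 1/2) and the Matthews correlation coefficient, for the positive
#' class (short-term survival), plus macro-averaged precision/recall/F1.
#' Zero-denominator metrics are reported as 0 with a warning; a single-class
#' truth vector gives `NA` AUC/MCC with a warning.
#'
#' @param y_true,y_pred binary labels (factor `short`/`long` or 0/1).
#' @param y_prob predicted positive-class probabilities (for AUC; optional).
#' @return Named numeric of class `metric_panel`.
#' @export
confusion_metrics <- function(y_true, y_pred, y_prob = NULL) {
  yt <- as_y01(y_true); yp <- as_y01(y_pred)
  if (length(yt) != length(yp)) stopf("y_true and y_pred lengths differ")
  tp <- sum(yt == 1 & yp == 1); tn <- sum(yt == 0 & yp == 0)
  fp <- sum(yt == 0 & yp == 1); fn <- sum(yt == 1 & yp == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator); reporting 0", what); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  prec_neg <- safe_div(tn, tn + fn, "negative-class precision")
  rec_neg <- safe_div(tn, tn + fp, "negative-class recall")
  f1_neg <- if (prec_neg + rec_neg == 0) 0 else
    2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  single_class <- length(unique(yt)) < 2
  if (single_class)
    warnf("y_true has a single class; AUC and MCC are undefined")
  mcc <- if (single_class) NA_real_ else {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) { warnf("MCC undefined (zero denominator); reporting 0"); 0 }
    else (tp * tn - fp * fn) / den
  }
  auc <- if (single_class || is.null(y_prob)) NA_real_ else
    mann_whitney_auc(yt, y_prob)
  structure(c(accuracy = (tp + tn) / length(yt), precision = precision,
              recall = recall, f1 = f1, auc = auc, mcc = mcc,
              precision_macro = (precision + prec_neg) / 2,
              recall_macro = (recall + rec_neg) / 2,
              f1_macro = (f1 + f1_neg) / 2),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

# AUC as the Mann-Whitney pair statistic (ties counted 1/2), via midranks.
mann_whitney_auc <- function(y01, prob) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  r <- rank(prob)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps thresholds over the unique predicted probabilities in descending
#' order; the trapezoidal area over the returned points equals the
#' Mann-Whitney AUC.
#'
#' @param y_true binary labels with both classes present.
#' @param y_prob positive-class probabilities.
#' @return Data frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1), non-decreasing in both coordinates.
#' @export
roc_points <- function(y_true, y_prob) {
  yt <- as_y01(y_true)
  if (length(unique(yt)) < 2) stopf("ROC needs both classes in y_true")
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  th <- sort(unique(y_prob), decreasing = TRUE)
  pts <- t(vapply(th, function(t0) {
    c(fpr = sum(yt == 0 & y_prob >= t0) / n0,
      tpr = sum(yt == 1 & y_prob >= t0) / n1)
  }, numeric(2)))
  out <- rbind(c(fpr = 0, tpr = 0), pts)
  out <- as.data.frame(out)
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1)
    out <- rbind(out, data.frame(fpr = 1, tpr = 1))
  out
}

#' Trapezoidal area under ROC points
#' @param pts result of [roc_points()].
#' @return Scalar area.
#' @export
roc_auc_trapezoid <- function(pts) {
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' One leave-one-out cross-validation pass
#'
#' For each subject: z-score normalization fitted on the other n-1 subjects,
#' optional RF-RFE (inside the fold by default), optional inner-CV tuning,
#' gradient-boosting fit, and prediction of the held-out subject. With
#' `paper_faithful = TRUE`, normalization and selection are fitted once on
#' the full dataset before the folds (a leakage warning is logged). If a
#' training fold is single-class, that fold predicts the majority class
#' with a warning.
#'
#' @param table a `feature_table`.
#' @param config an [eval_config()].
#' @param trial_seed integer seed for this trial's stochastic components.
#' @return Data frame: `subject`, `y_true`, `y_prob`, `y_pred`.
#' @export
loocv_run <- function(table, config = eval_config(), trial_seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x_raw
  y01 <- as_y01(table$labels)
  n <- nrow(x)
  if (n < 2) stopf("need at least two subjects")
  if (length(unique(y01)) < 2) stopf("both classes must be present")

  global_sel <- NULL; global_std <- NULL; gb_args <- config$gboost
  if (isTRUE(config$paper_faithful)) {
    warnf(paste("paper_faithful mode: feature selection%s fitted on the",
                "full dataset before cross-validation (information leak)"),
          if (isTRUE(config$tune)) " and tuning" else "")
    global_std <- standardize_cols(x)
    xs <- global_std$x
    if (isTRUE(config$rfe))
      global_sel <- rf_rfe(xs, y01, n_select = config$n_select,
                           step_fraction = config$step_fraction,
                           n_trees = config$rfe_trees,
                           seed = derive_seed(trial_seed, 0))$selected
    if (isTRUE(config$tune)) {
      xt <- if (is.null(global_sel)) xs else xs[, global_sel, drop = FALSE]
      best <- tune_hyperparameters(
        xt, y01, grid = config$grid %||% default_gboost_grid(),
        inner_folds = config$inner_folds,
        seed = derive_seed(trial_seed, 1))$best
      gb_args <- modifyList(gb_args, as.list(best))
    }
  }

  prob <- numeric(n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    ytr <- y01[tr_idx]
    if (length(unique(ytr)) < 2) {
      warnf("training fold %d is single-class; predicting majority class", i)
      prob[i] <- mean(ytr)
      next
    }
    if (isTRUE(config$paper_faithful)) {
      std <- global_std
      xtr <- std$x[tr_idx, , drop = FALSE]
      xte <- std$x[i, , drop = FALSE]
      sel <- global_sel
      gb <- gb_args
    } else {
      std <- standardize_cols(x[tr_idx, , drop = FALSE])
      xtr <- std$x
      xte <- standardize_cols(x[i, , drop = FALSE], std$center,
                              std$scale)$x
      sel <- if (isTRUE(config$rfe))
        rf_rfe(xtr, ytr, n_select = config$n_select,
               step_fraction = config$step_fraction,
               n_trees = config$rfe_trees,
               seed = derive_seed(trial_seed, i))$selected
      gb <- gb_args
      if (isTRUE(config$tune)) {
        xt <- if (is.null(sel)) xtr else xtr[, sel, drop = FALSE]
        best <- tune_hyperparameters(
          xt, ytr, grid = config$grid %||% default_gboost_grid(),
          inner_folds = config$inner_folds,
          seed = derive_seed(trial_seed, 10000 + i))$best
        gb <- modifyList(gb, as.list(best))
      }
    }
    if (!is.null(sel)) {
      xtr <- xtr[, sel, drop = FALSE]
      xte <- xte[, sel, drop = FALSE]
    }
    fit <- do.call(fit_gboost, c(list(x = xtr, y = ytr,
                                      seed = derive_seed(trial_seed,
                                                         20000 + i)),
                                 gb))
    prob[i] <- predict(fit, xte, type = "prob")
  }
  data.frame(subject = table$subject_ids, y_true = y01, y_prob = prob,
             y_pred = as.integer(prob >= 0.5))
}

#' Repeated leave-one-out cross-validation
#'
#' Runs [loocv_run()] `n_trials` times with trial seeds derived from
#' `base_seed` (trial-to-trial variation comes from reseeding the
#' stochastic components: RFE forests and boosting subsampling; the LOOCV
#' folds themselves are deterministic), computes the metric panel per trial
#' and its mean/SD, and exports ROC points.
#'
#' @param table a `feature_table`.
#' @param config an [eval_config()].
#' @param n_trials number of repetitions (the emulated protocol uses 50).
#' @param base_seed integer seed.
#' @return Object of class `cv_report`: `trials` (per-subject predictions
#'   per trial), `per_trial` (metric panel per trial), `mean`, `sd`,
#'   `roc`, `config`, `seeds`.
#' @export
repeated_trials <- function(table, config = eval_config(), n_trials = 50,
                            base_seed = 1) {
  if (n_trials < 1) stopf("n_trials must be >= 1")
  seeds <- vapply(seq_len(n_trials), function(t) derive_seed(base_seed, t),
                  integer(1))
  trials <- vector("list", n_trials)
  panels <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    res <- loocv_run(table, config, trial_seed = seeds[t])
    trials[[t]] <- res
    panels[[t]] <- suppressWarnings(
      confusion_metrics(res$y_true, res$y_pred, res$y_prob))
  }
  per_trial <- do.call(rbind, lapply(panels, unclass))
  roc_src <- if (identical(config$pool_roc, "all"))
    do.call(rbind, trials) else trials[[1]]
  roc <- roc_points(roc_src$y_true, roc_src$y_prob)
  structure(list(trials = trials, per_trial = as.data.frame(per_trial),
                 mean = colMeans(per_trial),
                 sd = apply(per_trial, 2, sd),
                 roc = roc, config = config, seeds = seeds,
                 n_trials = n_trials),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d LOOCV trial(s), n=%d subjects>\n",
              x$n_trials, nrow(x$trials[[1]])))
  panel <- rbind(mean = x$mean, sd = x$sd)
  print(round(panel[, c("accuracy", "precision", "recall", "f1", "auc",
                        "mcc")], 4))
  invisible(x)
}

#' Plot the ROC curve or per-trial accuracies of a CV report
#'
#' @param x a `cv_report`.
#' @param which `"roc"` or `"trials"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_report <- function(x, which = c("roc", "trials"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
         ylab = "true positive rate",
         main = sprintf("ROC (AUC %.3f)", roc_auc_trapezoid(x$roc)), ...)
    abline(0, 1, lty = 3)
  } else {
    acc <- x$per_trial$accuracy
    plot(seq_along(acc), acc, type = "b", xlab = "LOOCV trial",
         ylab = "accuracy",
         main = sprintf("per-trial accuracy (mean %.3f)", mean(acc)), ...)
    abline(h = mean(acc), lty = 2)
  }
  invisible(x)
}
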
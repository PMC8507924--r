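# From-scratch decision-tree ensemble stack. The per-tree CART growing
# (variance-reduction or Gini splits) is compiled code under src/; bootstrap
# draws, forest aggregation, the boosting loop and RFE live here.

as_matrix_x <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stopf("non-finite feature values")
  x
}

# Binary response as 0/1 with "short" (the clinically urgent class) positive.
as_y01 <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- factor(as.character(y))
    if (all(c("short", "long") %in% levels(y)))
      y <- factor(y, levels = c("long", "short"))
    if (nlevels(y) != 2) stopf("labels must have exactly two levels")
    as.integer(y) - 1L
  } else {
    if (!all(y %in% c(0, 1))) stopf("numeric labels must be 0/1")
    as.integer(y)
  }
}

#' Fit a CART regression tree
#'
#' Greedy variance-reduction (SSE) splits at midpoints between distinct
#' feature values; leaf value is the mean target. Deterministic given the
#' input order.
#'
#' @param x feature matrix (samples x features).
#' @param r numeric targets.
#' @param max_depth maximum depth (0 = unlimited).
#' @param min_leaf minimum training samples per leaf.
#' @return Object of class `cart_tree`.
#' @export
fit_regression_tree <- function(x, r, max_depth = 3, min_leaf = 1) {
  x <- as_matrix_x(x)
  if (any(!is.finite(r))) stopf("non-finite targets")
  if (nrow(x) < 1) stopf("need at least one sample")
  tr <- .cpp_grow_tree(x, as.numeric(r), seq_len(nrow(x)), 0L,
                       as.integer(max_depth), as.integer(min_leaf),
                       ncol(x), 1L, 1L)
  structure(list(nodes = tr, feature_names = colnames(x),
                 max_depth = max_depth, min_leaf = min_leaf),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- check_feature_layout(newdata, object$feature_names)
  .cpp_predict_tree(object$nodes, newdata)$value
}

#' @export
print.cart_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$feature))
  cat(sprintf("<cart_tree: %d nodes (%d leaves), max_depth %s>\n",
              length(x$nodes$feature), n_leaf, x$max_depth))
  invisible(x)
}

check_feature_layout <- function(newdata, feature_names) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(colnames(newdata))) {
    if (!all(feature_names %in% colnames(newdata)))
      stopf("newdata is missing feature(s): %s",
            paste(setdiff(feature_names, colnames(newdata))[1:3],
                  collapse = ", "))
    newdata <- newdata[, feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(feature_names)) {
    stopf("newdata has %d columns; model was trained on %d features",
          ncol(newdata), length(feature_names))
  }
  newdata
}

#' Fit a random forest of classification trees
#'
#' Bootstrap-aggregated Gini-impurity CART trees with `mtry` candidate
#' features per node; the forest predicts the class selected by most trees.
#' Per-feature importances are total Gini decreases averaged over trees and
#' normalized to sum 1. Deterministic given `seed`.
#'
#' @param x feature matrix.
#' @param y binary labels (factor or 0/1; both classes required).
#' @param n_trees number of trees.
#' @param mtry candidate features per node (default `floor(sqrt(p))`).
#' @param min_leaf minimum samples per leaf.
#' @param max_depth maximum depth (0 = unlimited).
#' @param bootstrap draw a bootstrap sample per tree (disable to fit each
#'   tree on the full sample).
#' @param seed integer seed.
#' @return Object of class `rf_model` with `trees`, `importances`,
#'   `oob_indices`.
#' @export
fit_random_forest <- function(x, y, n_trees = 200, mtry = NULL,
                              min_leaf = 1, max_depth = 0,
                              bootstrap = TRUE, seed = 1) {
  x <- as_matrix_x(x)
  y01 <- as_y01(y)
  if (length(unique(y01)) < 2) stopf("both classes must be present")
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  imp <- numeric(p)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tr <- .cpp_grow_tree(x, as.numeric(y01), rows, 1L,
                           as.integer(max_depth), as.integer(min_leaf),
                           as.integer(mtry), as.integer(seed), t)
      imp <- imp + tr$importance
      tr$leaf_of <- NULL
      trees[[t]] <- tr
      oob[[t]] <- setdiff(seq_len(n), rows)
    }
  })
  s <- sum(imp)
  importances <- setNames(if (s > 0) imp / s else imp, colnames(x))
  structure(list(trees = trees, importances = importances,
                 oob_indices = oob, feature_names = colnames(x),
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- check_feature_layout(newdata, object$feature_names)
  votes <- rowMeans(vapply(object$trees, function(tr)
    as.numeric(.cpp_predict_tree(tr, newdata)$value >= 0.5),
    numeric(nrow(newdata))))
  if (type == "prob") votes else as.integer(votes >= 0.5)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model: %d trees, mtry %d, %d features>\n",
              x$n_trees, x$mtry, length(x$feature_names)))
  top <- sort(x$importances, decreasing = TRUE)[1:min(5, length(x$importances))]
  cat("top importances:\n"); print(round(top, 4))
  invisible(x)
}

#' Random-forest recursive feature elimination
#'
#' Repeatedly fits a random forest on the remaining features and removes the
#' `ceiling(step_fraction * remaining)` lowest-importance ones (at least 1
#' per iteration, never overshooting below `n_select`) until exactly
#' `n_select` features remain. Importance ties are broken by feature name
#' order. Deterministic given `seed`.
#'
#' @param x feature matrix with column names.
#' @param y binary labels.
#' @param n_select target number of features (default 60).
#' @param step_fraction fraction of remaining features removed per
#'   iteration (default 0.1).
#' @param n_trees,mtry,min_leaf forest configuration per iteration.
#' @param seed integer seed.
#' @return Object of class `rfe_result`: `selected` (column order of `x`),
#'   `elimination_trace` (data frame), `seed`.
#' @export
rf_rfe <- function(x, y, n_select = 60, step_fraction = 0.1,
                   n_trees = 200, mtry = NULL, min_leaf = 1, seed = 1) {
  x <- as_matrix_x(x)
  if (n_select > ncol(x))
    stopf("n_select (%d) exceeds the number of features (%d)",
          n_select, ncol(x))
  if (n_select < 1) stopf("n_select must be >= 1")
  remaining <- colnames(x)
  trace <- list(); it <- 0
  while (length(remaining) > n_select) {
    it <- it + 1
    fm <- fit_random_forest(x[, remaining, drop = FALSE], y,
                            n_trees = n_trees, mtry = mtry,
                            min_leaf = min_leaf,
                            seed = derive_seed(seed, it))
    k <- min(max(1L, ceiling(step_fraction * length(remaining))),
             length(remaining) - n_select)
    drop_feats <- remaining[order(fm$importances, remaining)][seq_len(k)]
    remaining <- remaining[!remaining %in% drop_feats]
    trace[[it]] <- data.frame(iteration = it, removed = length(drop_feats),
                              remaining = length(remaining))
  }
  structure(list(selected = remaining,
                 elimination_trace = if (length(trace))
                   do.call(rbind, trace)
                 else data.frame(iteration = integer(0),
                                 removed = integer(0),
                                 remaining = integer(0)),
                 seed = seed),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result: %d features selected in %d iterations>\n",
              length(x$selected), nrow(x$elimination_trace)))
  invisible(x)
}

#' Fit a logistic gradient boosting classifier
#'
#' Stage-wise additive boosting of depth-limited CART regression trees on
#' the logistic loss: the initial score is the log-odds of the class
#' prevalence; each stage fits a tree to the current residuals
#' `y - sigmoid(F)` on a seeded subsample and replaces each leaf value by
#' the Newton step `sum(r) / sum(p (1 - p))` over the leaf (denominator
#' floored at 1e-12, step clipped to `|gamma| <= 10`); the score advances by
#' `learning_rate` times the tree. Deterministic given `seed`.
#'
#' @param x feature matrix.
#' @param y binary labels (both classes required).
#' @param n_estimators number of boosting stages `M`.
#' @param learning_rate shrinkage `nu` in (0, 1].
#' @param max_depth tree depth.
#' @param subsample fraction of samples per stage in (0, 1].
#' @param min_leaf minimum samples per leaf.
#' @param seed integer seed.
#' @return Object of class `gboost` with `f0`, `trees`, the training
#'   log-loss trace, and the fit configuration.
#' @export
fit_gboost <- function(x, y, n_estimators = 100, learning_rate = 0.1,
                       max_depth = 2, subsample = 1, min_leaf = 3,
                       seed = 1) {
  x <- as_matrix_x(x)
  y01 <- as_y01(y)
  if (length(unique(y01)) < 2) stopf("both classes must be present")
  if (learning_rate <= 0 || learning_rate > 1)
    stopf("learning_rate must be in (0, 1]")
  if (subsample <= 0 || subsample > 1) stopf("subsample must be in (0, 1]")
  n <- nrow(x)
  pbar <- mean(y01)
  f0 <- log(pbar / (1 - pbar))
  fscore <- rep(f0, n)
  trees <- vector("list", n_estimators)
  loss <- numeric(n_estimators)
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      p <- stats::plogis(fscore)
      rows <- if (subsample < 1)
        sort(sample.int(n, max(2L, floor(subsample * n))))
      else seq_len(n)
      r <- y01 - p
      tr <- .cpp_grow_tree(x, r, rows, 0L, as.integer(max_depth),
                           as.integer(min_leaf), ncol(x),
                           as.integer(seed), m)
      # Newton leaf updates over the (sub)sampled training rows
      leaf_tr <- tr$leaf_of[rows]
      w <- p[rows] * (1 - p[rows])
      num <- tapply(r[rows], leaf_tr, sum)
      den <- tapply(w, leaf_tr, sum)
      gamma <- num / pmax(den, 1e-12)
      gamma <- pmin(pmax(gamma, -10), 10)
      leaves <- as.integer(names(gamma))
      tr$value[leaves] <- as.numeric(gamma)
      tr$leaf_of <- NULL
      trees[[m]] <- tr
      fscore <- fscore + learning_rate *
        .cpp_predict_tree(tr, x)$value
      pm <- stats::plogis(fscore)
      loss[m] <- -mean(y01 * log(pmax(pm, 1e-15)) +
                         (1 - y01) * log(pmax(1 - pm, 1e-15)))
    }
  })
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 n_estimators = n_estimators, max_depth = max_depth,
                 subsample = subsample, min_leaf = min_leaf, seed = seed,
                 feature_names = colnames(x), train_loss = loss,
                 train_score = fscore, y01 = y01),
            class = "gboost")
}

#' Predict from a gradient boosting classifier
#'
#' @param object a [fit_gboost()] model.
#' @param newdata feature matrix with the training feature layout.
#' @param type `"prob"` (sigmoid of the additive score), `"link"` (raw
#'   score) or `"class"` (probability >= 0.5).
#' @param ... unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.gboost <- function(object, newdata,
                           type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  newdata <- check_feature_layout(newdata, object$feature_names)
  score <- rep(object$f0, nrow(newdata))
  for (tr in object$trees)
    score <- score + object$learning_rate *
      .cpp_predict_tree(tr, newdata)$value
  switch(type,
         link = score,
         prob = stats::plogis(score),
         class = as.integer(stats::plogis(score) >= 0.5))
}

#' @export
print.gboost <- function(x, ...) {
  cat(sprintf(
    "<gboost: M=%d, depth=%d, nu=%g, subsample=%g | final train log-loss %.4f>\n",
    x$n_estimators, x$max_depth, x$learning_rate, x$subsample,
    if (x$n_estimators) x$train_loss[x$n_estimators] else NA))
  invisible(x)
}

#' @export
summary.gboost <- function(object, ...) {
  use <- table(unlist(lapply(object$trees, function(tr)
    tr$feature[!is.na(tr$feature)])))
  top <- sort(use, decreasing = TRUE)
  top_named <- setNames(as.integer(top),
                        object$feature_names[as.integer(names(top))])
  out <- list(config = object[c("n_estimators", "learning_rate",
                                "max_depth", "subsample", "min_leaf")],
              final_train_loss = if (object$n_estimators)
                object$train_loss[object$n_estimators] else NA_real_,
              split_counts = top_named)
  class(out) <- "summary.gboost"
  out
}

#' @export
print.summary.gboost <- function(x, ...) {
  cat(sprintf("gboost fit: M=%d, nu=%g, depth=%d, subsample=%g\n",
              x$config$n_estimators, x$config$learning_rate,
              x$config$max_depth, x$config$subsample))
  cat(sprintf("final training log-loss: %.4f\n", x$final_train_loss))
  cat("most-used split features:\n")
  print(head(x$split_counts, 10))
  invisible(x)
}

#' @export
residuals.gboost <- function(object, ...) {
  object$y01 - stats::plogis(object$train_score)
}

#' @export
plot.gboost <- function(x, ...) {
  plot(seq_along(x$train_loss), x$train_loss, type = "l",
       xlab = "boosting stage", ylab = "training log-loss",
       main = "gboost training loss", ...)
  invisible(x)
}

#' Serialize a fitted gradient-boosting model to JSON
#'
#' Writes the tree structures, scalars and seed so a fit can be stored as
#' plain text and reloaded with [read_gboost()]. Missing child/feature
#' slots of leaf nodes are encoded as -1.
#'
#' @param model a [fit_gboost()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gboost <- function(model, path) {
  stopifnot(inherits(model, "gboost"))
  enc_tree <- function(tr) list(
    feature = ifelse(is.na(tr$feature), -1L, tr$feature),
    threshold = ifelse(is.na(tr$threshold), -1, tr$threshold),
    left = ifelse(is.na(tr$left), -1L, tr$left),
    right = ifelse(is.na(tr$right), -1L, tr$right),
    value = tr$value, n = tr$n)
  ser <- list(
    f0 = model$f0, learning_rate = model$learning_rate,
    n_estimators = model$n_estimators, max_depth = model$max_depth,
    subsample = model$subsample, min_leaf = model$min_leaf,
    seed = model$seed, feature_names = model$feature_names,
    train_loss = model$train_loss, trees = lapply(model$trees, enc_tree))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a gradient-boosting model written by [write_gboost()]
#'
#' @param path JSON file.
#' @return A `gboost` object (prediction-capable; training residual state
#'   is not stored).
#' @export
read_gboost <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_tree <- function(tr) list(
    feature = ifelse(tr$feature < 0, NA_integer_, as.integer(tr$feature)),
    threshold = ifelse(tr$threshold < 0 & tr$feature < 0, NA_real_,
                       tr$threshold),
    left = ifelse(tr$left < 0, NA_integer_, as.integer(tr$left)),
    right = ifelse(tr$right < 0, NA_integer_, as.integer(tr$right)),
    value = as.numeric(tr$value), n = as.integer(tr$n))
  trees <- if (is.data.frame(ser$trees))
    lapply(seq_len(nrow(ser$trees)), function(i)
      dec_tree(lapply(ser$trees, `[[`, i)))
  else lapply(ser$trees, dec_tree)
  structure(list(f0 = ser$f0, trees = trees,
                 learning_rate = ser$learning_rate,
                 n_estimators = ser$n_estimators,
                 max_depth = ser$max_depth, subsample = ser$subsample,
                 min_leaf = ser$min_leaf, seed = ser$seed,
                 feature_names = ser$feature_names,
                 train_loss = ser$train_loss),
            class = "gboost")
}

#' Default gradient-boosting hyperparameter grid
#'
#' @return Data frame over learning rate, tree depth, stage count and
#'   subsample fraction.
#' @export
default_gboost_grid <- function() {
  expand.grid(learning_rate = c(0.05, 0.1, 0.3), max_depth = 1:3,
              n_estimators = c(50, 100, 200), subsample = c(0.8, 1.0))
}

#' Tune gradient-boosting hyperparameters by stratified inner CV
#'
#' Evaluates each grid row by stratified `inner_folds`-fold cross-validation
#' accuracy on the given data; the best mean accuracy wins, with ties broken
#' toward the smaller `(n_estimators, max_depth, learning_rate)`.
#'
#' @param x feature matrix.
#' @param y binary labels.
#' @param grid data frame of configurations (see [default_gboost_grid()]).
#' @param inner_folds number of folds.
#' @param seed integer seed (fold assignment and fits).
#' @return List: `best` (one-row data frame), `cv` (grid with accuracies).
#' @export
tune_hyperparameters <- function(x, y, grid = default_gboost_grid(),
                                 inner_folds = 5, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0) stopf("empty hyperparameter grid")
  x <- as_matrix_x(x)
  y01 <- as_y01(y)
  n <- nrow(x)
  folds <- with_seed(derive_seed(seed, 0), {
    f <- integer(n)
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      f[idx] <- rep_len(seq_len(inner_folds), length(idx))
    }
    f
  })
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0; total <- 0
    for (k in seq_len(inner_folds)) {
      tr <- folds != k; te <- folds == k
      if (!any(te) || length(unique(y01[tr])) < 2) next
      fit <- fit_gboost(x[tr, , drop = FALSE], y01[tr],
                        n_estimators = grid$n_estimators[g],
                        learning_rate = grid$learning_rate[g],
                        max_depth = grid$max_depth[g],
                        subsample = grid$subsample[g],
                        seed = derive_seed(seed, g * 100 + k))
      pred <- predict(fit, x[te, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == y01[te]); total <- total + sum(te)
    }
    acc[g] <- if (total > 0) correct / total else NA_real_
  }
  ord <- order(-acc, grid$n_estimators, grid$max_depth, grid$learning_rate)
  best <- grid[ord[1], , drop = FALSE]
  list(best = best, cv = cbind(grid, accuracy = acc))
}
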
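test_that("regression tree handles constant and perfectly split targets", {
  x <- matrix(1:6, 6, 1)
  t0 <- fit_regression_tree(x, rep(2.5, 6))
  expect_equal(length(t0$nodes$feature), 1)  # single leaf
  expect_equal(predict(t0, x), rep(2.5, 6))

  t1 <- fit_regression_tree(matrix(1:4, 4, 1), c(0, 0, 1, 1), max_depth = 1)
  thr <- t1$nodes$threshold[1]
  expect_gt(thr, 2); expect_lt(thr, 3)
  expect_equal(predict(t1, matrix(c(1, 2, 3, 4), 4, 1)), c(0, 0, 1, 1))

  expect_error(fit_regression_tree(matrix(c(1, NA), 2, 1), c(0, 1)),
               "finite")
})

test_that("greedy stump splits attain the exhaustive-search optimum", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:6, 1); p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    r <- rnorm(n)
    tree <- fit_regression_tree(x, r, max_depth = 1)
    pred <- predict(tree, x)
    expect_equal(sum((r - pred)^2), best_stump_sse(x, r), tolerance = 1e-12)
  }
})

test_that("forest importances are a normalized, signal-tracking ranking", {
  set.seed(5)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- as.integer(x[, 1] > 0)
  hits <- 0
  for (s in 1:10) {
    fm <- fit_random_forest(x, y, n_trees = 100, seed = s)
    expect_true(all(fm$importances >= 0))
    expect_equal(sum(fm$importances), 1, tolerance = 1e-12)
    if (which.max(fm$importances) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # label independent of features: importance spread stays flat
  set.seed(6)
  y0 <- sample(rep(0:1, 40))
  x0 <- matrix(rnorm(80 * 10), 80, 10)
  fm0 <- fit_random_forest(x0, y0, n_trees = 200, seed = 11)
  expect_lt(max(fm0$importances), 3 * mean(fm0$importances))

  expect_error(fit_random_forest(x, rep(1L, 60)), "classes")
})

test_that("forest fits are deterministic given the seed", {
  set.seed(2)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.integer(x[, 2] - x[, 3] > 0)
  f1 <- fit_random_forest(x, y, n_trees = 25, seed = 77)
  f2 <- fit_random_forest(x, y, n_trees = 25, seed = 77)
  expect_identical(f1$importances, f2$importances)
  expect_identical(predict(f1, x), predict(f2, x))
  # an unbagged full-mtry single tree separates pure-partition data
  xp <- matrix(c(1:8), 8, 1)
  yp <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fd <- fit_random_forest(xp, yp, n_trees = 1, mtry = 1,
                          bootstrap = FALSE, seed = 1)
  expect_equal(predict(fd, xp, type = "class"), yp)
})

test_that("RFE eliminates to the exact target with a decreasing trace", {
  set.seed(10)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- as.integer(x[, 1] + x[, 2] > 0)

  id <- rf_rfe(x, y, n_select = 10, seed = 1)
  expect_equal(id$selected, colnames(x))
  expect_equal(nrow(id$elimination_trace), 0)

  hits <- 0
  for (s in 1:10) {
    sel <- rf_rfe(x, y, n_select = 2, step_fraction = 0.2, n_trees = 150,
                  seed = s)
    expect_length(sel$selected, 2)
    expect_true(all(diff(sel$elimination_trace$remaining) < 0))
    expect_equal(min(sel$elimination_trace$remaining), 2)
    if (setequal(sel$selected, c("f01", "f02"))) hits <- hits + 1
  }
  expect_gte(hits, 9)

  expect_error(rf_rfe(x, y, n_select = 11), "exceeds")
})

test_that("boosting base score, separable fit and loss monotonicity hold", {
  set.seed(3)
  x <- matrix(rnorm(40), 40, 1)
  y <- as.integer(x[, 1] > 0)

  m0 <- fit_gboost(x, y, n_estimators = 0)
  expect_equal(predict(m0, x), rep(mean(y), 40), tolerance = 1e-12)

  m1 <- fit_gboost(x, y, n_estimators = 50, learning_rate = 0.5,
                   max_depth = 1, min_leaf = 1, subsample = 1)
  expect_equal(mean(predict(m1, x, type = "class") == y), 1.0)

  set.seed(4)
  x2 <- matrix(rnorm(50 * 8), 50, 8)
  y2 <- as.integer(x2[, 1] + rnorm(50, 0, 0.7) > 0)
  m2 <- fit_gboost(x2, y2, n_estimators = 120, learning_rate = 0.1,
                   subsample = 1, seed = 5)
  expect_true(all(diff(m2$train_loss) <= 1e-9))

  expect_error(fit_gboost(x, y, learning_rate = 1.5), "learning_rate")
  expect_error(fit_gboost(x, rep(0L, 40)), "classes")
})

test_that("shrinking the learning rate at constant nu*M stabilizes the fit", {
  set.seed(6)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- as.integer(x[, 1] - x[, 2] + rnorm(60, 0, 0.5) > 0)
  pa <- predict(fit_gboost(x, y, n_estimators = 100, learning_rate = 0.1,
                           subsample = 1, seed = 1), x)
  pb <- predict(fit_gboost(x, y, n_estimators = 200, learning_rate = 0.05,
                           subsample = 1, seed = 1), x)
  expect_lt(mean(abs(pa - pb)), 0.05)
  expect_gt(cor(pa, pb), 0.98)
})

test_that("probabilities are a monotone map of the additive score", {
  set.seed(7)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.integer(x[, 1] > 0)
  m <- fit_gboost(x, y, n_estimators = 20, seed = 2)
  xnew <- matrix(rnorm(50 * 4), 50, 4)
  link <- predict(m, xnew, type = "link")
  prob <- predict(m, xnew, type = "prob")
  expect_equal(order(link), order(prob))
  expect_equal(prob, stats::plogis(link), tolerance = 1e-12)
  expect_equal(unname(stats::plogis(0)), 0.5)
  expect_error(predict(m, xnew[, 1:3]), "features")
})

test_that("from-scratch ensembles track established-library counterparts", {
  skip_if_not_installed("randomForest")
  skip_if_not_installed("xgboost")
  set.seed(8)
  gen <- function(n) {
    x <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(NULL, sprintf("g%02d", 1:12)))
    y <- as.integer(x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.8) > 0)
    list(x = x, y = y)
  }
  tr <- gen(80); te <- gen(400)

  ours_rf <- fit_random_forest(tr$x, tr$y, n_trees = 300, seed = 1)
  acc_ours_rf <- mean(predict(ours_rf, te$x, type = "class") == te$y)
  ref_rf <- randomForest::randomForest(tr$x, factor(tr$y), ntree = 300)
  acc_ref_rf <- mean(as.integer(as.character(
    predict(ref_rf, te$x))) == te$y)
  expect_lt(abs(acc_ours_rf - acc_ref_rf), 0.1)

  ours_gb <- fit_gboost(tr$x, tr$y, n_estimators = 100,
                        learning_rate = 0.1, max_depth = 2, seed = 1)
  acc_ours_gb <- mean(predict(ours_gb, te$x, type = "class") == te$y)
  ref_gb <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 2, eta = 0.1,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(tr$x, label = tr$y), nrounds = 100,
    verbose = 0)
  acc_ref_gb <- mean((predict(ref_gb, xgboost::xgb.DMatrix(te$x)) >= 0.5)
                     == te$y)
  expect_lt(abs(acc_ours_gb - acc_ref_gb), 0.1)
})

test_that("gboost models round-trip through JSON", {
  set.seed(11)
  x <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, sprintf("j%d", 1:5)))
  y <- as.integer(x[, 1] + rnorm(30, 0, 0.5) > 0)
  m <- fit_gboost(x, y, n_estimators = 40, max_depth = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_gboost(m, f)
  m2 <- read_gboost(f)
  xn <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(NULL, sprintf("j%d", 1:5)))
  expect_equal(predict(m2, xn), predict(m, xn), tolerance = 1e-12)
  expect_equal(m2$f0, m$f0, tolerance = 1e-15)
})

test_that("hyperparameter tuning honors the grid and its tie-breaks", {
  set.seed(9)
  x <- matrix(rnorm(40 * 3), 40, 3)
  x[, 1] <- c(runif(20, -2, -0.5), runif(20, 0.5, 2))  # margin at 0
  y <- as.integer(x[, 1] > 0)  # separable: every config reaches accuracy 1

  single <- data.frame(learning_rate = 0.2, max_depth = 2,
                       n_estimators = 30, subsample = 1)
  res1 <- tune_hyperparameters(x, y, grid = single, seed = 1)
  expect_equal(res1$best$learning_rate, 0.2)

  grid <- expand.grid(learning_rate = c(0.05, 0.1), max_depth = c(1, 2),
                      n_estimators = 40, subsample = 1)
  res <- tune_hyperparameters(x, y, grid = grid, seed = 2)
  expect_true(all(res$cv$accuracy == 1))
  expect_equal(res$best$max_depth, 1)
  expect_equal(res$best$learning_rate, 0.05)

  # argmax property: the winner is at least as good as every grid point
  set.seed(10)
  xn <- matrix(rnorm(50 * 6), 50, 6)
  yn <- as.integer(xn[, 1] + rnorm(50, 0, 1.2) > 0)
  resn <- tune_hyperparameters(xn, yn, grid = grid, seed = 3)
  expect_gte(max(resn$cv$accuracy),
             resn$cv$accuracy[which.min(resn$cv$accuracy)])
  expect_equal(resn$cv$accuracy[with(resn$cv,
    which(learning_rate == resn$best$learning_rate &
            max_depth == resn$best$max_depth &
            n_estimators == resn$best$n_estimators &
            subsample == resn$best$subsample))],
    max(resn$cv$accuracy))

  expect_error(tune_hyperparameters(x, y, grid = data.frame()), "grid")
})
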
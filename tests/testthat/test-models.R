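test_that("z-score normalization uses training statistics (population SD)", {
  tr <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2)
  te <- matrix(c(2, 4, 5, 9), ncol = 2)
  zs <- zscore_fit_apply(tr, te)
  expect_equal(zs$train[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(zs$train[3, 1], 4), 1.2247)
  expect_equal(zs$train[, 2], c(0, 0, 0))            # constant column
  expect_true(zs$stats$zero_variance[2])
  expect_equal(zs$test[1, 1], 0)                      # test value at train mean
  expect_equal(zs$test[, 2], c(0, 0))
})

test_that("stratified split honours per-class rounding and determinism", {
  y <- rep(c("case", "control"), c(28, 45))
  sp <- stratified_split(y, 0.7, seed = 1)
  expect_length(sp$test, 21)   # round(.7*28)=20, round(.7*45)=32 -> 21 held out
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(all(c("case", "control") %in% y[sp$test]))
  expect_identical(sp, stratified_split(y, 0.7, seed = 1))
  expect_false(identical(sp$train, stratified_split(y, 0.7, seed = 2)$train))
  expect_error(stratified_split(y, 1), "train_frac")
  expect_error(stratified_split(rep("a", 10)), "classes")
  expect_error(stratified_split(c("a", rep("b", 9))), ">= 2")
})

test_that("classification metrics reproduce the reconstructed confusion table", {
  # TP=8 FN=0 TN=11 FP=2 at threshold .5
  y <- c(rep(TRUE, 8), rep(FALSE, 13))
  p <- c(rep(0.9, 8), rep(0.1, 11), rep(0.9, 2))
  m <- classification_metrics(y, p)
  expect_equal(m$accuracy, 19 / 21)
  expect_equal(round(m$accuracy, 3), 0.905)
  expect_equal(m$sensitivity, 1)
  expect_equal(round(m$specificity, 3), 0.846)
  expect_equal(m$precision, 0.8)
  expect_equal(round(m$F1, 3), 0.889)
  expect_equal(round(m$balanced_accuracy, 3), 0.923)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
})

test_that("AUROC follows the rank formulation, ties and all", {
  expect_equal(classification_metrics(c(TRUE, TRUE, FALSE, FALSE),
                                      c(0.1, 0.3, 0.2, 0.4))$auroc, 0.25)
  expect_equal(classification_metrics(c(TRUE, FALSE), c(1, 0))$auroc, 1)
  expect_error(classification_metrics(c(TRUE, TRUE), c(0.2, 0.4)), "single")
  expect_error(classification_metrics(c(TRUE, FALSE), c(0.2, 1.4)), "0, 1")
  # property: equals the exhaustive pairwise oracle on small tied inputs
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    p <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(classification_metrics(y, p)$auroc, oracle_auroc(p, y))
  }
})

test_that("regression metrics match hand arithmetic and definitions", {
  y <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  ident <- regression_metrics(y, y)
  expect_equal(ident$per_score$MSE, c(0, 0))
  expect_equal(ident$per_score$R2, c(1, 1))
  mean_pred <- cbind(a = rep(2, 3), b = rep(5, 3))
  expect_equal(regression_metrics(y, mean_pred)$per_score$R2, c(0, 0))
  hand <- regression_metrics(cbind(c(1, 2, 3)), cbind(c(2, 2, 2)))
  expect_equal(hand$per_score$MSE, 2 / 3)
  expect_equal(hand$per_score$MAE, 2 / 3)
  expect_equal(hand$per_score$R2, 0)
  expect_equal(hand$per_score$RMSE^2, hand$per_score$MSE, tolerance = 1e-9)
  flat <- regression_metrics(cbind(rep(1, 3)), cbind(c(1, 1, 2)))
  expect_true(is.na(flat$per_score$R2))
  expect_equal(flat$average$undefined_R2, 1)
  expect_error(regression_metrics(y, y[, 1, drop = FALSE]), "shape")
})

test_that("classifier bank separates strong signal and flags one winner", {
  set.seed(1)
  n <- 200; p <- 50
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x[y, 1:3] <- x[y, 1:3] + 3
  sp <- stratified_split(y, 0.7, seed = 1)
  zs <- zscore_fit_apply(x[sp$train, ], x[sp$test, ])
  rep <- train_eval_classifiers(zs$train, y[sp$train], zs$test, y[sp$test],
                                seed = 1)
  expect_equal(nrow(rep), 5)
  expect_equal(sum(rep$selected), 1)
  expect_gte(rep$auroc[rep$model == "lasso"], 0.95)
  expect_equal(rep$balanced_accuracy,
               (rep$sensitivity + rep$specificity) / 2, tolerance = 1e-12)
  one <- train_eval_classifiers(zs$train, y[sp$train], zs$test, y[sp$test],
                                models = "logistic", seed = 1)
  expect_equal(nrow(one), 1)
  expect_error(train_eval_classifiers(zs$train, rep(TRUE, length(sp$train)),
                                      zs$test, y[sp$test]), "degenerate")
})

test_that("severity bank recovers noiseless linear targets and reports six rows", {
  set.seed(2)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("F", 1:p)))
  B <- matrix(0, p, 5); B[1:5, ] <- rnorm(25)
  Y <- x %*% B
  colnames(Y) <- c("physical", "capability", "cgi", "vabs", "viq")
  out <- train_eval_severity(x[1:42, ], Y[1:42, ], x[43:60, ], Y[43:60, ],
                             seed = 1)
  expect_equal(nrow(out$report), 6)
  expect_equal(sum(out$report$selected), 1)
  expect_gt(out$report$R2[out$report$model == "mlr"], 0.99)
  expect_equal(out$report$RMSE^2 * 0 + out$per_score$RMSE^2,
               out$per_score$MSE, tolerance = 1e-9)
  expect_true(all(out$per_score$R2 <= 1 + 1e-12))
  expect_error(train_eval_severity(x[1:42, 1:3], Y[1:42, ], x[43:60, 1:3],
                                   Y[43:60, ], models = "pls"), "PLS")
})
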
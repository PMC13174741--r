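#' Z-score normalization fitted on training data
#'
#' Centers and scales every column of `train` to mean 0, SD 1 (population-SD
#' convention, i.e. denominator `n`), and applies the training statistics to
#' `test`. Zero-variance training columns are mapped to all-zero and flagged.
#'
#' @param train,test numeric matrices with matching columns (`test` optional).
#' @return list with `train`, `test` (or `NULL`), and `stats` (center, scale,
#'   `zero_variance` logical per column).
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("train needs >= 2 rows")
  center <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2L, center)^2))
  zero_var <- scl <= .Machine$double.eps
  scl[zero_var] <- 1
  tr <- sweep(sweep(train, 2L, center), 2L, scl, `/`)
  tr[, zero_var] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2L, center), 2L, scl, `/`)
    te[, zero_var] <- 0
  }
  list(train = tr, test = te,
       stats = list(center = center, scale = scl, zero_variance = zero_var))
}

#' Stratified train/test split
#'
#' Per class, `round(train_frac * n_class)` samples go to training; the split
#' is disjoint and exhaustive, and both classes are represented on both sides.
#'
#' @param labels factor or character vector of class labels.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1")
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < 2L)) stop("every class needs >= 2 members")
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    # round() after snapping away float fuzz, so e.g. 0.7 * 45 -> 31.5 -> 32
    n_tr <- round(round(train_frac * length(idx), 8))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both sides represented
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Rank-based (Mann-Whitney) AUROC with midrank tie correction.
auroc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: single-class labels")
  r <- rank(score)  # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from probabilities
#'
#' Confusion-matrix metrics at a fixed probability threshold plus AUROC by the
#' rank (Mann-Whitney) formulation with midrank tie handling.
#'
#' @param y_true binary labels: logical, 0/1, or a factor whose second level
#'   is the positive class.
#' @param y_prob predicted probabilities of the positive class, in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return one-row data frame: accuracy, sensitivity, specificity, precision,
#'   F1, balanced_accuracy, auroc.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  pos <- as_binary(y_true)
  if (any(y_prob < 0 | y_prob > 1)) stop("y_prob must lie in [0, 1]")
  if (length(unique(pos)) < 2L) stop("AUROC undefined: single-class labels")
  pred <- y_prob >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens)
        else NA_real_
  data.frame(accuracy = (tp + tn) / length(pos),
             sensitivity = sens, specificity = spec, precision = prec,
             F1 = f1, balanced_accuracy = (sens + spec) / 2,
             auroc = auroc_rank(y_prob, pos))
}

as_binary <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) return(y == levels(y)[2L])
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1))) stop("numeric y_true must be 0/1")
    return(y == 1)
  }
  f <- factor(y)
  f == levels(f)[2L]
}

# Stratified fold ids so cross-validation never sees a one-class fold.
stratified_foldid <- function(y, nfolds) {
  pos <- as_binary(y)
  fid <- integer(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(pos == cl))
    fid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fid
}

#' Train and evaluate the classification model bank
#'
#' Fits up to five classifiers on the training split and scores each on the
#' held-out test split: plain binomial logistic regression; LASSO-penalized
#' logistic regression evaluated at the penalty minimizing 10-fold
#' cross-validated deviance; a 500-tree random forest; an RBF-kernel SVM with
#' probability outputs; and gradient boosting (binary-logistic objective,
#' eta 0.1, depth 3, 100 rounds). The model with the highest test AUROC
#' (tie-break: balanced accuracy) is flagged `selected`.
#'
#' @param train_x,train_y,test_x,test_y normalized feature matrices and
#'   binary labels for the two disjoint splits.
#' @param models subset of `c("logistic", "lasso", "rf", "svm", "xgboost")`.
#' @param threshold decision threshold for the confusion metrics.
#' @param seed integer seed for the stochastic learners.
#' @return data frame, one metric row per model, plus `selected`.
#' @export
train_eval_classifiers <- function(train_x, train_y, test_x, test_y,
                                   models = c("logistic", "lasso", "rf",
                                              "svm", "xgboost"),
                                   threshold = 0.5, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  y_tr <- as_binary(train_y); y_te <- as_binary(test_y)
  if (length(unique(y_tr)) < 2L) stop("degenerate training labels")
  probs <- list()
  set.seed(seed)
  for (mod in models) {
    probs[[mod]] <- switch(mod,
      logistic = {
        df <- data.frame(y = as.integer(y_tr), train_x, check.names = FALSE)
        fit <- suppressWarnings(stats::glm(y ~ ., binomial(), data = df))
        as.numeric(suppressWarnings(stats::predict(
          fit, data.frame(test_x, check.names = FALSE), type = "response")))
      },
      lasso = {
        fid <- stratified_foldid(y_tr, 10L)
        cv <- glmnet::cv.glmnet(train_x, as.integer(y_tr),
                                family = "binomial", alpha = 1, foldid = fid)
        as.numeric(stats::predict(cv, test_x, s = "lambda.min",
                                  type = "response"))
      },
      rf = {
        fit <- randomForest::randomForest(train_x, factor(y_tr), ntree = 500)
        stats::predict(fit, test_x, type = "prob")[, "TRUE"]
      },
      svm = {
        fit <- e1071::svm(train_x, factor(y_tr), probability = TRUE)
        pr <- attr(stats::predict(fit, test_x, probability = TRUE),
                   "probabilities")
        pr[, "TRUE"]
      },
      xgboost = {
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.1,
                        max_depth = 3, nthread = 1),
          data = xgboost::xgb.DMatrix(train_x, label = as.integer(y_tr)),
          nrounds = 100, verbose = 0)
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(test_x)))
      })
  }
  rep <- do.call(rbind, lapply(names(probs), function(mod) {
    cbind(data.frame(model = mod, stringsAsFactors = FALSE),
          classification_metrics(y_te, pmin(pmax(probs[[mod]], 0), 1),
                                 threshold))
  }))
  best <- order(-rep$auroc, -rep$balanced_accuracy)[1L]
  rep$selected <- seq_len(nrow(rep)) == best
  rep
}
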
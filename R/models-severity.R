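#' Regression metrics per severity score
#'
#' Standard error summaries per target column plus their averages:
#' MSE, RMSE, MAE and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (negative when the model underperforms the
#' mean; undefined and flagged for a zero-variance truth column).
#'
#' @param y_true,y_pred numeric matrices of identical shape (columns =
#'   severity scores) or vectors.
#' @return list with `per_score` (data frame, one row per score) and
#'   `average` (one-row data frame of column means; R^2 averaged over defined
#'   scores only).
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch")
  if (nrow(y_true) < 2L) stop("need >= 2 samples per score")
  per <- do.call(rbind, lapply(seq_len(ncol(y_true)), function(j) {
    err <- y_true[, j] - y_pred[, j]
    mse <- mean(err^2)
    ss_tot <- sum((y_true[, j] - mean(y_true[, j]))^2)
    r2 <- if (ss_tot <= .Machine$double.eps) NA_real_
          else 1 - sum(err^2) / ss_tot
    data.frame(score = colnames(y_true)[j] %||% paste0("score", j),
               MSE = mse, RMSE = sqrt(mse), MAE = mean(abs(err)), R2 = r2,
               stringsAsFactors = FALSE)
  }))
  avg <- data.frame(MSE = mean(per$MSE), RMSE = mean(per$RMSE),
                    MAE = mean(per$MAE), R2 = mean(per$R2, na.rm = TRUE),
                    undefined_R2 = sum(is.na(per$R2)))
  list(per_score = per, average = avg)
}

## ---- minimal feed-forward network (2 hidden ReLU layers, Adam, MSE) ----
## Small dense networks on cohort-sized data need no external runtime; this
## is a direct implementation of backprop + Adam on matrices.

mlp_init <- function(p_in, p_out, hidden = c(64L, 32L)) {
  dims <- c(p_in, hidden, p_out)
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / fan_in)),
                    dims[l], dims[l + 1L]),
         b = rep(0, dims[l + 1L]))
  })
}

mlp_forward <- function(layers, x) {
  acts <- list(x)
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < n_l) pmax(z, 0) else z  # ReLU hidden, linear out
  }
  acts
}

mlp_fit <- function(x, y, hidden = c(64L, 32L), epochs = 100L,
                    batch_size = 16L, lr = 1e-3, seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x); y <- as.matrix(y)
  layers <- mlp_init(ncol(x), ncol(y), hidden)
  adam <- lapply(layers, function(l)
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(x)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acts <- mlp_forward(layers, x[idx, , drop = FALSE])
      n_l <- length(layers)
      delta <- 2 * (acts[[n_l + 1L]] - y[idx, , drop = FALSE]) / length(idx)
      t <- t + 1L
      for (l in rev(seq_len(n_l))) {
        gW <- t(acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        a <- adam[[l]]
        a$mW <- beta1 * a$mW + (1 - beta1) * gW
        a$vW <- beta2 * a$vW + (1 - beta2) * gW^2
        a$mb <- beta1 * a$mb + (1 - beta1) * gb
        a$vb <- beta2 * a$vb + (1 - beta2) * gb^2
        adam[[l]] <- a
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        layers[[l]]$W <- layers[[l]]$W -
          lr * (a$mW / corr1) / (sqrt(a$vW / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
      }
    }
  }
  structure(list(layers = layers), class = "proteoscout_mlp")
}

mlp_predict <- function(fit, x) {
  acts <- mlp_forward(fit$layers, as.matrix(x))
  acts[[length(acts)]]
}

#' Train and evaluate the multi-output severity model bank
#'
#' Six models predicting the five severity scores jointly from normalized
#' features: multivariate linear regression; partial least squares with five
#' components; a 500-tree random forest per score; per-score gradient
#' boosting (squared-error objective, 100 rounds, eta 0.1, depth 3); a
#' multi-task L1-penalized linear model (grouped multi-response lasso, penalty
#' chosen by five-fold cross-validation); and a feed-forward network with two
#' hidden ReLU layers of 64 and 32 units trained by Adam for 100 epochs at
#' batch size 16 under a squared-error loss. The model with the lowest average
#' test RMSE (tie-break: highest average R^2) is flagged `selected`.
#'
#' @param train_x,test_x normalized feature matrices.
#' @param train_y,test_y matrices of the severity scores (columns = scores).
#' @param models subset of `c("mlr", "pls", "rf", "xgboost", "lasso", "fnn")`.
#' @param pls_ncomp number of PLS components (requires `ncol(x) >= ncomp`).
#' @param seed integer seed.
#' @return list with `report` (one row per model: average metrics plus
#'   `selected`) and `per_score` (long data frame of per-score metrics).
#' @export
train_eval_severity <- function(train_x, train_y, test_x, test_y,
                                models = c("mlr", "pls", "rf", "xgboost",
                                           "lasso", "fnn"),
                                pls_ncomp = 5L, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.matrix(train_y); test_y <- as.matrix(test_y)
  q <- ncol(train_y)
  set.seed(seed)
  preds <- list()
  for (mod in models) {
    preds[[mod]] <- switch(mod,
      mlr = {
        fit <- stats::lm(train_y ~ ., data = data.frame(train_x,
                                                        check.names = FALSE))
        as.matrix(stats::predict(fit, data.frame(test_x, check.names = FALSE)))
      },
      pls = {
        if (ncol(train_x) < pls_ncomp)
          stop("PLS needs at least ", pls_ncomp, " features")
        fit <- mixOmics::pls(train_x, train_y, ncomp = pls_ncomp,
                             mode = "regression", scale = FALSE)
        pr <- stats::predict(fit, test_x)$predict
        pr[, , pls_ncomp]
      },
      rf = {
        do.call(cbind, lapply(seq_len(q), function(j) {
          fit <- randomForest::randomForest(train_x, train_y[, j], ntree = 500)
          stats::predict(fit, test_x)
        }))
      },
      xgboost = {
        do.call(cbind, lapply(seq_len(q), function(j) {
          fit <- xgboost::xgb.train(
            params = list(objective = "reg:squarederror", eta = 0.1,
                          max_depth = 3, nthread = 1),
            data = xgboost::xgb.DMatrix(train_x, label = train_y[, j]),
            nrounds = 100, verbose = 0)
          as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(test_x)))
        }))
      },
      lasso = {
        fid <- rep_len(seq_len(5L), nrow(train_x))[sample.int(nrow(train_x))]
        cv <- glmnet::cv.glmnet(train_x, train_y, family = "mgaussian",
                                foldid = fid)
        pr <- stats::predict(cv, test_x, s = "lambda.min")
        matrix(pr, nrow(test_x), q)
      },
      fnn = {
        fit <- mlp_fit(train_x, train_y, seed = seed)
        mlp_predict(fit, test_x)
      })
    colnames(preds[[mod]]) <- colnames(train_y)
  }
  per_score <- list(); avg_rows <- list()
  for (mod in names(preds)) {
    mtr <- regression_metrics(test_y, preds[[mod]])
    per_score[[mod]] <- cbind(model = mod, mtr$per_score)
    avg_rows[[mod]] <- cbind(data.frame(model = mod,
                                        stringsAsFactors = FALSE),
                             mtr$average)
  }
  report <- do.call(rbind, avg_rows)
  rownames(report) <- NULL
  best <- order(report$RMSE, -report$R2)[1L]
  report$selected <- seq_len(nrow(report)) == best
  list(report = report, per_score = do.call(rbind, per_score))
}
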
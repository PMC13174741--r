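make_masked <- function(n = 30, p = 12, frac = 0.1, seed = 2) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  inject_missingness(m, frac, seed = seed + 1)
}

test_that("imputers leave complete matrices and observed cells untouched", {
  m <- matrix(rnorm(60), 10, 6)
  for (meth in c("mean", "iterative_pca", "soft_svd", "hot_deck"))
    expect_equal(unclass(impute_matrix(m, meth)), m, ignore_attr = TRUE)
  mk <- make_masked()
  for (meth in c("mean", "iterative_pca", "soft_svd", "forest", "hot_deck")) {
    out <- impute_matrix(mk$data, meth, ntree = 10, max_cycles = 2)
    expect_false(anyNA(out))
    expect_identical(out[!mk$mask], mk$data[!mk$mask])  # bitwise equality
  }
})

test_that("column-mean imputation fills with the column mean", {
  m <- matrix(c(2, 4, NA, 1, 1, 1), ncol = 2)
  expect_equal(impute_matrix(m, "mean")[3, 1], 3.0, ignore_attr = TRUE)
})

test_that("all-missing columns are rejected by name", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("c", 1:4)))
  m[, 2] <- NA
  expect_error(impute_matrix(m, "mean"), "c2")
})

test_that("iterative PCA exactly recovers a rank-1 matrix", {
  set.seed(4)
  r1 <- outer(rnorm(40), rnorm(30))
  mk <- inject_missingness(r1, 0.1, seed = 5)
  out <- impute_matrix(mk$data, "iterative_pca", k = 1, tol = 1e-9,
                       max_iter = 5000)
  expect_lt(max(abs(out[mk$mask] - r1[mk$mask])), 1e-6)
})

test_that("soft-SVD objective is non-increasing across iterations", {
  mk <- make_masked(n = 25, p = 10, seed = 7)
  out <- impute_matrix(mk$data, "soft_svd")
  obj <- attr(out, "objective")
  expect_gt(length(obj), 1)
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("hot-deck values are observed donors, within label groups when given", {
  mk <- make_masked(n = 40, p = 8, seed = 9)
  out <- impute_matrix(mk$data, "hot_deck", seed = 3)
  for (j in which(colSums(mk$mask) > 0)) {
    donors <- mk$data[!is.na(mk$data[, j]), j]
    expect_true(all(out[mk$mask[, j], j] %in% donors))
  }
  grp <- rep(c("a", "b"), each = 20)
  outg <- impute_matrix(mk$data, "hot_deck", labels = grp, seed = 3)
  for (j in which(colSums(mk$mask) > 0)) {
    for (i in which(mk$mask[, j])) {
      donors <- mk$data[grp == grp[i], j]
      expect_true(outg[i, j] %in% donors[!is.na(donors)])
    }
  }
})

test_that("ensembles are deterministic, with replicate variation only for stochastic methods", {
  mk <- make_masked(seed = 12)
  ens_mean <- impute_ensemble(mk$data, "mean", M = 5, base_seed = 1)
  expect_length(ens_mean$replicates, 5)
  for (r in ens_mean$replicates[-1])
    expect_equal(unclass(r), unclass(ens_mean$replicates[[1]]),
                 ignore_attr = TRUE)
  ens_hd <- impute_ensemble(mk$data, "hot_deck", M = 5, base_seed = 1)
  vals <- sapply(ens_hd$replicates, function(r) r[mk$mask])
  expect_gt(max(apply(vals, 1, function(v) length(unique(v)))), 1)
  ens_hd2 <- impute_ensemble(mk$data, "hot_deck", M = 5, base_seed = 1)
  expect_equal(lapply(ens_hd$replicates, unclass),
               lapply(ens_hd2$replicates, unclass), ignore_attr = TRUE)
  expect_error(impute_ensemble(mk$data, "mean", M = 0), "M")
})

test_that("evaluation metrics match hand arithmetic and degenerate intervals", {
  truth <- matrix(c(2, 4, 6), 1)
  rep1 <- matrix(c(3, 4, 5), 1)
  mask <- matrix(TRUE, 1, 3)
  ev <- evaluate_imputation(truth, rep1, mask)
  expect_equal(ev$MAE, 2 / 3)
  expect_equal(ev$MSE, 2 / 3)
  expect_equal(ev$RMSE, sqrt(2 / 3))
  expect_equal(ev$RB, 0)
  expect_equal(ev$PB, 0)
  # deterministic ensemble, not exactly right -> zero-width intervals
  ens <- structure(list(replicates = list(rep1, rep1, rep1), method = "det",
                        seeds = 1:3), class = "imputed_ensemble")
  ev2 <- evaluate_imputation(truth, ens, mask)
  expect_equal(ev2$AW, 0)
  expect_equal(ev2$CR, 1 / 3)  # the exactly-imputed middle cell covers
  expect_error(evaluate_imputation(truth, rep1, matrix(FALSE, 1, 3)),
               "empty mask")
})

test_that("calibrated-noise ensembles reach nominal interval coverage", {
  set.seed(11)
  truth <- matrix(rnorm(1000), 100, 10)
  reps <- lapply(1:50, function(i) truth + matrix(rnorm(1000), 100, 10))
  ens <- structure(list(replicates = reps, method = "noise", seeds = 1:50),
                   class = "imputed_ensemble")
  ev <- evaluate_imputation(truth, ens, matrix(TRUE, 100, 10))
  expect_lt(abs(ev$CR - 0.95), 0.03)
})

test_that("report invariants hold and benchmarking shares one mask", {
  set.seed(3)
  m <- matrix(rnorm(600), 30, 20)
  rep <- benchmark_imputation(m, fraction = 0.1,
                              methods = c("mean", "iterative_pca", "hot_deck"),
                              M = 4, seed = 6)
  expect_equal(rep$MSE, rep$RMSE^2, tolerance = 1e-9)
  expect_true(all(rep$MAE <= rep$RMSE + 1e-12))
  expect_true(all(rep$CR >= 0 & rep$CR <= 1))
  expect_true(all(rep$AW >= 0))
  expect_equal(sum(rep$selected), 1)
  expect_equal(length(unique(rep$n)), 1)  # identical mask for every method

  single <- benchmark_imputation(m, methods = "mean", M = 2, seed = 6)
  expect_equal(nrow(single), 1)
  expect_true(single$selected)
  expect_equal(single$method, "mean")
})

test_that("low-rank structure beats the marginal mean baseline", {
  set.seed(5)
  m <- outer(rnorm(40), rnorm(25)) + outer(rnorm(40), rnorm(25)) +
    matrix(rnorm(1000, sd = 0.1), 40, 25)
  rep <- suppressWarnings(
    benchmark_imputation(m, fraction = 0.1,
                         methods = c("mean", "iterative_pca"), M = 1,
                         seed = 8, k = 4))
  expect_lt(rep$MAE[rep$method == "iterative_pca"],
            rep$MAE[rep$method == "mean"])
})
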
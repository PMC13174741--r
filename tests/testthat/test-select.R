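test_that("mixing-parameter tuning is deterministic and handles singleton grids", {
  set.seed(1)
  x <- matrix(rnorm(60 * 15), 60, 15)
  y <- rep(c(TRUE, FALSE), 30)
  expect_equal(as.numeric(tune_penalty_mixing(x, y, grid = 1.0)), 1.0)
  a1 <- tune_penalty_mixing(x, y, grid = c(0.25, 0.5, 1), seed = 3)
  a2 <- tune_penalty_mixing(x, y, grid = c(0.25, 0.5, 1), seed = 3)
  expect_equal(as.numeric(a1), as.numeric(a2))
  expect_length(attr(a1, "cv_auroc"), 3)
  expect_error(tune_penalty_mixing(x, y, grid = numeric(0)), "grid")
  expect_error(tune_penalty_mixing(x, y, grid = 1.5), "grid")
})

test_that("a dominant predictor is always selected; thresholding is monotone", {
  set.seed(2)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x[y, 1] <- x[y, 1] + 3
  st <- stability_select(x, y, alpha_star = 0.5, B = 30, threshold = 0.8,
                         seed = 7)
  expect_equal(unname(st$frequency["V1"]), 1.0)
  expect_true("V1" %in% st$retained)
  expect_true(all(st$frequency * st$B == round(st$frequency * st$B)))
  st0 <- stability_select(x, y, 0.5, B = 30, threshold = 1e-9, seed = 7)
  expect_setequal(st0$retained, names(st0$frequency)[st0$frequency > 0])
  # retained set shrinks (weakly) as the threshold rises
  for (thr in c(0.2, 0.5, 0.9)) {
    a <- names(st$frequency)[st$frequency >= thr]
    b <- names(st$frequency)[st$frequency >= thr + 0.05]
    expect_true(all(b %in% a))
  }
  # frequencies do not depend on column order (up to coordinate-descent
  # convergence fuzz near the selection boundary: allow one flip in B)
  perm <- sample(p)
  st_p <- stability_select(x[, perm], y, 0.5, B = 30, threshold = 0.8,
                           seed = 7)
  expect_lt(max(abs(st_p$frequency[names(st$frequency)] - st$frequency)),
            2 / 30)
  expect_equal(unname(st_p$frequency["V1"]), 1.0)
})

test_that("minimal depth matches manual traversal, fill-in rule included", {
  # feature 1 at depth 1 of tree A; absent from tree B (depth 2) -> (1+3)/2
  treeA <- data.frame(left = c(2, 4, 0, 0, 0), right = c(3, 5, 0, 0, 0),
                      split_var = c(2, 1, 0, 0, 0))
  treeB <- data.frame(left = c(2, 0, 4, 0, 0), right = c(3, 0, 5, 0, 0),
                      split_var = c(2, 0, 3, 0, 0))
  md <- minimal_depth_profile(list(treeA, treeB), 3)
  expect_equal(unname(md), c(2, 0, 2))  # f2 at every root; f3: (3+1)/2
  # a feature in no tree of a depth-3 forest scores 4
  deep <- data.frame(left = c(2, 3, 4, 0, 0, 0, 0),
                     right = c(5, 6, 7, 0, 0, 0, 0),
                     split_var = c(1, 2, 1, 0, 0, 0, 0))
  expect_equal(unname(minimal_depth_profile(list(deep), 3))[3], 4)
  expect_error(minimal_depth_profile(list(), 3), "empty")
})

test_that("minimal depth agrees with an independent recursive oracle", {
  set.seed(5)
  for (rep in 1:10) {
    x <- matrix(rnorm(200 * 6), 200, 6)
    y <- x[, 1] * 2 + rnorm(200)
    fit <- randomForest::randomForest(x, y, ntree = 5, nodesize = 20)
    got <- minimal_depth_profile(fit, 6)
    trees <- lapply(1:5, function(k) {
      tr <- randomForest::getTree(fit, k)
      data.frame(left = tr[, "left daughter"], right = tr[, "right daughter"],
                 split_var = tr[, "split var"])
    })
    want <- rowMeans(sapply(trees, oracle_min_depth, p = 6))
    expect_equal(unname(got), want)
  }
})

test_that("depth selection finds the feature a score copies and respects bounds", {
  set.seed(2)
  x <- matrix(rnorm(80 * 30), 80, 30, dimnames = list(NULL, paste0("F", 1:30)))
  sc <- cbind(s1 = x[, 7], s2 = rnorm(80), s3 = rnorm(80), s4 = rnorm(80),
              s5 = rnorm(80))
  dp <- depth_select(x, sc, B = 5, ntree = 50, seed = 1)
  expect_equal(rownames(dp$importance_z)[which.max(dp$importance_z[, "s1"])],
               "F7")
  expect_true("F7" %in% dp$retained)
  # importance_z is standardized within each score
  expect_equal(unname(colMeans(dp$importance_z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(dp$importance_z, 2, sd)), rep(1, 5),
               tolerance = 1e-9)
  none <- depth_select(x, sc, B = 2, ntree = 20, z_threshold = Inf, seed = 1)
  expect_length(none$retained, 0)
  allsc <- depth_select(x, sc, B = 2, ntree = 20, aggregate = "all", seed = 1)
  expect_true(length(allsc$retained) <= length(
    depth_select(x, sc, B = 2, ntree = 20, aggregate = "any", seed = 1)$retained))
})

test_that("candidate merging unions with provenance tags", {
  m <- merge_candidates(c("A", "B"), c("B", "C"))
  expect_equal(m$feature, c("A", "B", "C"))
  expect_equal(m$source[m$feature == "B"], "both")
  expect_equal(m$source[m$feature == "A"], "classification")
  big <- merge_candidates(paste0("c", 1:32), paste0("s", 1:234))
  expect_equal(nrow(big), 266)
  expect_equal(nrow(merge_candidates(character(0), character(0))), 0)
})
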
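#' Tune the elastic-net mixing parameter by cross-validated AUROC
#'
#' For every mixing value `alpha` on the grid, a penalized logistic model is
#' cross-validated (stratified folds shared across the grid) and scored by
#' AUROC at its CV-optimal penalty strength; the `alpha` with the highest
#' AUROC wins, ties going to the smallest `alpha`. Note that `alpha = 0`
#' (ridge) never zeroes coefficients, so it is a poor choice for the
#' downstream selection-frequency counting; a warning is raised if it wins.
#'
#' @param x feature matrix; `y` binary labels.
#' @param grid candidate mixing values in `[0, 1]`.
#' @param folds number of cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @return `alpha_star`, with attribute `cv_auroc` (named vector over the
#'   grid).
#' @export
tune_penalty_mixing <- function(x, y, grid = seq(0, 1, by = 0.1), folds = 5L,
                                seed = 1L) {
  if (!length(grid) || any(grid < 0 | grid > 1))
    stop("grid must be a nonempty subset of [0, 1]")
  x <- as.matrix(x)
  yb <- as_binary(y)
  set.seed(seed)
  fid <- stratified_foldid(yb, folds)
  auc <- vapply(grid, function(a) {
    cv <- glmnet::cv.glmnet(x, as.integer(yb), family = "binomial",
                            alpha = a, foldid = fid, type.measure = "auc")
    max(cv$cvm)
  }, numeric(1))
  names(auc) <- format(grid)
  alpha_star <- grid[order(-auc, grid)[1L]]
  if (alpha_star == 0)
    warning("alpha_star = 0 (ridge): coefficients are never exactly zero, ",
            "so selection frequencies will be degenerate")
  structure(alpha_star, cv_auroc = auc)
}

#' Bootstrapped stability selection with a penalized logistic model
#'
#' Draws `B` bootstrap samples of the participants (with replacement),
#' refits the penalized logistic model at the fixed mixing `alpha_star` on
#' each (penalty strength re-chosen by cross-validation inside the bootstrap
#' unless `lambda` is supplied), and records which features enter with a
#' nonzero coefficient. Features selected in at least `threshold * B`
#' bootstraps are retained. Bootstraps that draw a single class are redrawn
#' (at most 10 attempts each).
#'
#' @param x feature matrix; `y` binary labels.
#' @param alpha_star elastic-net mixing parameter (from
#'   [tune_penalty_mixing()]).
#' @param B number of bootstrap iterations.
#' @param threshold retention frequency in `(0, 1]` (0 retains every feature
#'   ever selected).
#' @param lambda optional fixed penalty strength; `NULL` re-tunes per
#'   bootstrap.
#' @param lambda_rule which CV penalty to select inside each bootstrap:
#'   `"lambda.1se"` (default; the strongest penalty within one standard error
#'   of the CV optimum, the conservative choice for support recovery) or
#'   `"lambda.min"` (the prediction-optimal penalty, which admits many more
#'   spurious coefficients per fit).
#' @param folds CV folds for the per-bootstrap penalty tuning (default 10,
#'   the cross-validation default of the underlying implementation).
#' @param seed integer seed.
#' @return Object of class `"stability_profile"`: list with `frequency`
#'   (named, multiples of `1/B`), `retained` (character vector), `B`,
#'   `alpha_star`, `threshold`.
#' @export
stability_select <- function(x, y, alpha_star, B = 200L, threshold = 0.8,
                             lambda = NULL,
                             lambda_rule = c("lambda.1se", "lambda.min"),
                             folds = 10L, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  if (B < 1L) stop("B must be >= 1")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  yb <- as_binary(y)
  n <- nrow(x)
  set.seed(seed)
  count <- stats::setNames(numeric(ncol(x)), colnames(x))
  redraws <- 0L
  for (b in seq_len(B)) {
    for (attempt in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(yb[idx])) == 2L) break
      redraws <- redraws + 1L
      if (attempt == 10L) stop("bootstrap produced a single class 10 times")
    }
    xb <- x[idx, , drop = FALSE]; ybb <- yb[idx]
    if (is.null(lambda)) {
      fid <- stratified_foldid(ybb, folds)
      fit <- glmnet::cv.glmnet(xb, as.integer(ybb), family = "binomial",
                               alpha = alpha_star, foldid = fid)
      co <- stats::coef(fit, s = lambda_rule)
    } else {
      fit <- glmnet::glmnet(xb, as.integer(ybb), family = "binomial",
                            alpha = alpha_star, lambda = lambda)
      co <- stats::coef(fit)
    }
    nz <- rownames(co)[as.numeric(co) != 0]
    nz <- setdiff(nz, "(Intercept)")
    count[nz] <- count[nz] + 1
  }
  freq <- count / B
  structure(list(frequency = freq,
                 retained = names(freq)[freq >= threshold & freq > 0],
                 B = B, alpha_star = as.numeric(alpha_star),
                 threshold = threshold, redraws = redraws),
            class = "stability_profile")
}

## ---- minimal depth ----

# Normalize a forest into a list of trees; each tree is a data frame with
# columns left, right (row index of daughters, 0 = terminal) and split_var
# (feature index, 0 = terminal).
forest_trees <- function(forest) {
  if (inherits(forest, "randomForest")) {
    lapply(seq_len(forest$ntree), function(k) {
      tr <- randomForest::getTree(forest, k, labelVar = FALSE)
      data.frame(left = tr[, "left daughter"],
                 right = tr[, "right daughter"],
                 split_var = tr[, "split var"])
    })
  } else if (is.list(forest)) {
    lapply(forest, function(tr) {
      tr <- as.data.frame(tr)
      stopifnot(all(c("left", "right", "split_var") %in% names(tr)))
      tr
    })
  } else stop("unsupported forest object")
}

# Depth of every node (root = 0) by traversal from the root (node 1).
node_depths <- function(tree) {
  depth <- rep(NA_real_, nrow(tree))
  depth[1L] <- 0
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (ch in c(tree$left[i], tree$right[i])) {
      if (ch > 0L) { depth[ch] <- depth[i] + 1; queue <- c(queue, ch) }
    }
  }
  depth
}

#' Mean minimal depth of every feature across a forest
#'
#' The minimal depth of feature `f` in a tree is the depth (root = 0) of the
#' shallowest node splitting on `f`; a tree that never uses `f` contributes
#' the fill-in value `max depth of that tree + 1`. The profile is the mean
#' over all trees.
#'
#' @param forest a `randomForest` fit, or a list of plain trees (data frames
#'   with columns `left`, `right`, `split_var`; 0 marks terminal nodes, and
#'   `split_var` holds the feature index of each internal node).
#' @param p_features number of features (indices `1..p_features`).
#' @return named numeric vector of mean minimal depths (names `V1..Vp` or the
#'   forest's feature names when available).
#' @export
minimal_depth_profile <- function(forest, p_features) {
  trees <- forest_trees(forest)
  if (!length(trees)) stop("empty forest")
  depth_sum <- numeric(p_features)
  for (tr in trees) {
    d <- node_depths(tr)
    fill <- max(d) + 1
    md <- rep(fill, p_features)
    internal <- tr$split_var > 0L
    if (any(internal)) {
      agg <- tapply(d[internal], tr$split_var[internal], min)
      md[as.integer(names(agg))] <- agg
    }
    depth_sum <- depth_sum + md
  }
  out <- depth_sum / length(trees)
  nms <- if (inherits(forest, "randomForest") &&
             !is.null(rownames(forest$importance)))
    rownames(forest$importance) else paste0("V", seq_len(p_features))
  stats::setNames(out, nms)
}

#' Minimal-depth feature selection from bootstrap forests per severity score
#'
#' For each severity score, random forests are trained on `B` bootstrap
#' samples and the per-feature mean minimal depth is averaged across the `B`
#' forests. Importance is the negated mean minimal depth (shallow = more
#' influential), Z-scored across features within each score; a feature is
#' retained when its importance Z exceeds `z_threshold` for at least one
#' score (`aggregate = "any"`) or for every score (`"all"`).
#'
#' @param x feature matrix; `scores` matrix of severity scores (columns =
#'   scores).
#' @param B bootstrap forests per score.
#' @param z_threshold retention threshold on the importance Z-score
#'   (strict `>`).
#' @param ntree trees per forest.
#' @param aggregate `"any"` or `"all"` across scores.
#' @param seed integer seed.
#' @return Object of class `"depth_profile"`: list with `mean_minimal_depth`
#'   and `importance_z` (feature x score matrices), `retained`, `B`.
#' @export
depth_select <- function(x, scores, B = 50L, z_threshold = 2, ntree = 100L,
                         aggregate = c("any", "all"), seed = 1L) {
  aggregate <- match.arg(aggregate)
  if (B < 1L) stop("B must be >= 1")
  x <- as.matrix(x); scores <- as.matrix(scores)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- ncol(x); n <- nrow(x)
  set.seed(seed)
  mmd <- matrix(0, p, ncol(scores),
                dimnames = list(colnames(x), colnames(scores)))
  for (j in seq_len(ncol(scores))) {
    acc <- numeric(p)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- randomForest::randomForest(x[idx, , drop = FALSE],
                                        scores[idx, j], ntree = ntree)
      acc <- acc + minimal_depth_profile(fit, p)
    }
    mmd[, j] <- acc / B
  }
  imp <- -mmd
  z <- apply(imp, 2L, function(v) {
    s <- stats::sd(v)
    if (s <= .Machine$double.eps) rep(0, length(v)) else (v - mean(v)) / s
  })
  dimnames(z) <- dimnames(mmd)
  hits <- z > z_threshold
  keep <- if (aggregate == "any") rowSums(hits) > 0L
          else rowSums(hits) == ncol(scores)
  structure(list(mean_minimal_depth = mmd, importance_z = z,
                 retained = rownames(z)[keep], B = B,
                 z_threshold = z_threshold, aggregate = aggregate),
            class = "depth_profile")
}

#' Merge candidate feature sets with provenance tags
#'
#' Set union with stable first-seen ordering; each feature is tagged by the
#' source set(s) it came from (`"both"` when it appears in more than one).
#'
#' @param classification,severity character vectors of feature ids (either
#'   may be empty).
#' @return data frame with columns `feature` and `source`.
#' @export
merge_candidates <- function(classification = character(0),
                             severity = character(0)) {
  classification <- unique(as.character(classification))
  severity <- unique(as.character(severity))
  feats <- unique(c(classification, severity))
  if (!length(feats))
    return(data.frame(feature = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  src <- ifelse(feats %in% classification & feats %in% severity, "both",
                ifelse(feats %in% classification, "classification",
                       "severity"))
  data.frame(feature = feats, source = src, stringsAsFactors = FALSE)
}
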
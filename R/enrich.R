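#' Read a GMT gene-set collection
#'
#' One set per tab-separated line: set name, description, then members.
#' Duplicate members within a set are counted once.
#'
#' @param path path to a GMT file.
#' @param source_tag optional provenance tag stored as an attribute.
#' @return named list of character vectors (class `"gene_set_collection"`).
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                   i))
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  structure(sets, class = "gene_set_collection", source = source_tag)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the overlap `k` between the query and the
#' background-restricted set is scored by the upper-tail hypergeometric
#' probability `P(X >= k)` with `n` query genes drawn from a background of
#' `N` containing `K` set members; the enrichment fold is `(k/n) / (K/N)`.
#' P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param background character vector: the measured universe.
#' @param collection a [read_gmt()] collection (or plain named list of
#'   character vectors).
#' @return data frame with one row per set: `term`, `k`, `n`, `K`, `N`, `p`,
#'   `p_adj`, `fold`.
#' @export
ora_test <- function(query, background, collection) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query genes absent from background: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  n <- length(query); N <- length(background)
  rows <- lapply(names(collection), function(term) {
    set_bg <- intersect(collection[[term]], background)
    K <- length(set_bg)
    k <- length(intersect(query, set_bg))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (K > 0L) (k / n) / (K / N) else 0
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p, fold = fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("term", "k", "n", "K", "N", "p", "p_adj", "fold")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Filter enrichment rows by significance and fold
#'
#' Retains rows with `p_adj` strictly below `p_adj_max` and fold strictly
#' above `fold_min`, sorted by ascending adjusted p-value.
#'
#' @param rows a data frame from [ora_test()].
#' @param p_adj_max adjusted-p cutoff (strict `<`).
#' @param fold_min enrichment-fold cutoff (strict `>`).
#' @return the filtered, sorted data frame.
#' @export
filter_terms <- function(rows, p_adj_max = 0.01, fold_min = 1.5) {
  keep <- rows$p_adj < p_adj_max & rows$fold > fold_min
  out <- rows[keep, , drop = FALSE]
  out[order(out$p_adj), , drop = FALSE]
}

#' Split features into up- and down-regulated groups
#'
#' Stratifies candidate features by the sign of the case-minus-control mean
#' difference, the grouping used before enrichment so each direction is
#' analyzed independently.
#'
#' @param x feature matrix (samples x features).
#' @param y binary labels (second factor level / `TRUE` = case).
#' @param features character vector of feature ids to stratify.
#' @return list with `up` and `down` character vectors.
#' @export
stratify_by_direction <- function(x, y, features) {
  pos <- as_binary(y)
  features <- intersect(features, colnames(x))
  d <- colMeans(x[pos, features, drop = FALSE], na.rm = TRUE) -
    colMeans(x[!pos, features, drop = FALSE], na.rm = TRUE)
  list(up = features[d > 0], down = features[d <= 0])
}
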
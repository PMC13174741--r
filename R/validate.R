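#' Read an expression matrix with case/control phenotypes
#'
#' The expression TSV has gene ids in the first column and samples as the
#' remaining columns; the phenotype TSV maps `sample_id` to `phenotype`
#' (`case` / `control`) and, optionally, a `progression` label for cases
#' (slow / average / rapid).
#'
#' @param path expression TSV path.
#' @param phenotype_path phenotype TSV path.
#' @return list of class `"expression_set"` with `expr` (gene x sample
#'   matrix, restricted and ordered to the phenotyped samples), `phenotype`
#'   (factor, levels control/case) and `progression` (character or `NA`).
#' @export
read_expression_matrix <- function(path, phenotype_path) {
  em <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- em[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene row(s): ",
                        paste(unique(dup), collapse = ", "))
  mat <- as.matrix(em[, -1L, drop = FALSE])
  rownames(mat) <- genes
  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(ph)))
    stop("phenotype file needs 'sample_id' and 'phenotype' columns")
  missing_s <- setdiff(ph$sample_id, colnames(mat))
  if (length(missing_s))
    stop("phenotype sample(s) not in matrix: ",
         paste(missing_s, collapse = ", "))
  mat <- mat[, ph$sample_id, drop = FALSE]
  structure(list(expr = mat,
                 phenotype = factor(ph$phenotype,
                                    levels = c("control", "case")),
                 progression = if ("progression" %in% names(ph))
                   ph$progression else rep(NA_character_, nrow(ph))),
            class = "expression_set")
}

#' Per-gene ROC analysis
#'
#' AUROC via the rank-sum (Mann-Whitney) formulation with midrank tie
#' handling, in both orientations: `directed` scores cases-above-controls,
#' `discriminative` is `max(a, 1 - a)` and so direction-free. Curve points
#' are generated from the sorted unique thresholds.
#'
#' @param values numeric expression values, one per sample.
#' @param phenotype binary labels (second factor level / `TRUE` = case).
#' @return list with `auroc_directed`, `auroc_discriminative`, and `curve`
#'   (data frame of FPR/TPR points).
#' @export
gene_auroc <- function(values, phenotype) {
  pos <- as_binary(phenotype)
  if (!any(pos) || all(pos)) stop("need at least one case and one control")
  a <- auroc_rank(values, pos)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  curve <- do.call(rbind, lapply(thr, function(t) {
    pred <- values >= t
    data.frame(FPR = sum(pred & !pos) / sum(!pos),
               TPR = sum(pred & pos) / sum(pos))
  }))
  list(auroc_directed = a, auroc_discriminative = max(a, 1 - a),
       curve = curve)
}

#' Rank candidate genes by discriminative AUROC
#'
#' Maps candidates onto the expression matrix (unmapped genes are reported,
#' not fatal), computes the per-gene direction-free AUROC, sorts descending,
#' flags genes strictly above `auroc_min`, and returns the `top_n`.
#'
#' @param eset an `"expression_set"` (or list with `expr` and `phenotype`).
#' @param candidate_genes character vector of gene ids.
#' @param auroc_min flagging threshold (strict `>`).
#' @param top_n number of top genes to return.
#' @return list with `table` (all mapped genes, sorted), `top` (first
#'   `top_n` ids), `unmapped`.
#' @export
rank_candidates <- function(eset, candidate_genes, auroc_min = 0.8,
                            top_n = 6L) {
  candidate_genes <- unique(as.character(candidate_genes))
  mapped <- intersect(candidate_genes, rownames(eset$expr))
  unmapped <- setdiff(candidate_genes, mapped)
  if (!length(mapped)) stop("no candidate gene maps to the expression matrix")
  rows <- lapply(mapped, function(gn) {
    r <- gene_auroc(eset$expr[gn, ], eset$phenotype)
    data.frame(gene = gn, auroc_directed = r$auroc_directed,
               auroc_discriminative = r$auroc_discriminative,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$auroc_discriminative, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab$flagged <- tab$auroc_discriminative > auroc_min
  if (top_n > nrow(tab))
    warning("top_n exceeds the number of mapped candidates; returning all")
  list(table = tab, top = utils::head(tab$gene, top_n), unmapped = unmapped)
}

#' Expression summary by progression group
#'
#' Per gene and group (control, slow, average, rapid): mean, SD and n, plus a
#' monotonicity flag raised when the group means are strictly ordered along
#' control -> slow -> average -> rapid (in either direction, over the
#' non-empty groups).
#'
#' @param eset an `"expression_set"` with progression labels for cases.
#' @param genes genes to summarize (must be rows of the matrix).
#' @return data frame, one row per gene x group, plus `monotone` (per gene).
#' @export
progression_summary <- function(eset, genes) {
  pos <- as_binary(eset$phenotype)
  if (all(is.na(eset$progression[pos])))
    stop("progression labels missing for cases")
  genes <- intersect(genes, rownames(eset$expr))
  grp <- ifelse(pos, eset$progression, "control")
  levels_ord <- c("control", "slow", "average", "rapid")
  out <- list()
  for (gn in genes) {
    v <- eset$expr[gn, ]
    means <- numeric(0)
    for (g in levels_ord) {
      vv <- v[!is.na(grp) & grp == g]
      out[[length(out) + 1L]] <- data.frame(
        gene = gn, group = g, n = length(vv),
        mean = if (length(vv)) mean(vv) else NA_real_,
        sd = if (length(vv) > 1L) stats::sd(vv) else
          if (length(vv) == 1L) 0 else NA_real_,
        stringsAsFactors = FALSE)
      if (length(vv)) means <- c(means, mean(vv))
    }
    mono <- length(means) >= 2L &&
      (all(diff(means) > 0) || all(diff(means) < 0))
    idx <- length(out) - 3:0
    for (i in idx) out[[i]]$monotone <- mono
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
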
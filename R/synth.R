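#' Cohort generator configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' reproduce the structure of a two-platform CSF proteomic study of CLN3
#' disease: an antibody-panel (PEA) assay covering all samples, a mass
#' spectrometry (MS) panel covering a partially overlapping subset, clinical
#' features measured on cases only, and five bounded severity scores.
#'
#' @param n_case,n_control number of case / control samples.
#' @param p_pea,p_ms,p_clin number of PEA-panel, MS-panel and clinical
#'   features.
#' @param n_biomarkers number of planted case-effect features (placed on the
#'   proteomic panels, each in a distinct correlation block).
#' @param effect_size standardized case-vs-control mean shift (Cohen's d) of
#'   the planted biomarkers.
#' @param n_severity_drivers number of proteomic features linearly driving the
#'   latent severity variable.
#' @param noise_sd residual standard deviation of the severity scores around
#'   the latent severity (latent scale; severity is standardized before the
#'   affine map into each score's range).
#' @param block_corr exchangeable within-block feature correlation, in
#'   `[0, 1)`.
#' @param block_size number of features per correlation block.
#' @param n_both_case,n_both_control samples assayed on both platforms;
#'   remaining cases are PEA-only, remaining controls are split into
#'   `n_ms_only_control` MS-only samples and PEA-only samples.
#' @param n_ms_only_control controls assayed on the MS platform only.
#' @param layout `"merged"` (union matrix with platform-block missingness for
#'   platform-absent samples, the study's structure) or `"complete"` (every
#'   sample carries every feature).
#' @param seed integer seed; the whole cohort is reproducible under it.
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_case = 28L, n_control = 30L,
                          p_pea = 1467L, p_ms = 3319L, p_clin = 226L,
                          n_biomarkers = 10L, effect_size = 1.0,
                          n_severity_drivers = 5L, noise_sd = 1.0,
                          block_corr = 0.3, block_size = 10L,
                          n_both_case = 20L, n_both_control = 10L,
                          n_ms_only_control = 15L,
                          layout = c("merged", "complete"),
                          seed = 1L) {
  layout <- match.arg(layout)
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              p_pea = as.integer(p_pea), p_ms = as.integer(p_ms),
              p_clin = as.integer(p_clin),
              n_biomarkers = as.integer(n_biomarkers),
              effect_size = effect_size,
              n_severity_drivers = as.integer(n_severity_drivers),
              noise_sd = noise_sd, block_corr = block_corr,
              block_size = as.integer(block_size),
              n_both_case = min(as.integer(n_both_case), as.integer(n_case)),
              n_both_control = min(as.integer(n_both_control),
                                   as.integer(n_control)),
              n_ms_only_control = as.integer(n_ms_only_control),
              layout = layout, seed = as.integer(seed))
  counts <- c("n_case", "n_control", "p_pea", "p_ms", "p_clin",
              "n_biomarkers", "n_severity_drivers")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a count >= 1", nm))
  }
  if (cfg$n_biomarkers > cfg$p_pea + cfg$p_ms)
    stop("n_biomarkers exceeds the number of proteomic features")
  if (cfg$n_severity_drivers > cfg$p_pea + cfg$p_ms - cfg$n_biomarkers)
    stop("n_severity_drivers exceeds the available proteomic features")
  if (cfg$block_corr < 0 || cfg$block_corr >= 1)
    stop("block_corr must lie in [0, 1)")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  cfg$n_ms_only_control <- min(cfg$n_ms_only_control,
                               cfg$n_control - cfg$n_both_control)
  class(cfg) <- "cohort_config"
  cfg
}

# Correlated Gaussian features: each block shares a latent factor so that
# cor(x_j, x_k) = rho within a block and 0 across blocks; marginal SD is 1.
block_gaussian <- function(n, p, rho, block_size) {
  n_blocks <- ceiling(p / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
  z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  x <- sqrt(rho) * z[, block_of, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
  attr(x, "block_of") <- block_of
  x
}

# Bounded severity score: standardized latent 'u' mapped affinely into the
# score's range and clipped at the edges; the clipped fraction is recorded.
bounded_score <- function(u, center, spread, lo, hi) {
  raw <- center + spread * u
  clipped <- mean(raw < lo | raw > hi)
  list(value = pmin(pmax(raw, lo), hi), clipped = clipped)
}

#' Simulate a two-platform case/control cohort with planted ground truth
#'
#' Draws correlated Gaussian feature blocks, shifts planted biomarker features
#' by `effect_size` in cases, and derives five severity scores from a latent
#' severity variable driven by designated proteomic features. Scores honour
#' the clinical instruments' ranges and directions: Physical impairment
#' (0-112) and CGI (6-35) increase with severity; Capability (1-14), VABS and
#' VIQ (both mean 100, SD 15) decrease.
#'
#' @param config a [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements
#'   \describe{
#'     \item{features}{sample x feature numeric matrix (`NA` = not measured
#'       under the `"merged"` layout).}
#'     \item{labels}{data frame with `sample_id`, `group` (`"case"` /
#'       `"control"`) and platform flags.}
#'     \item{severity}{data frame of the five severity scores for case
#'       samples.}
#'     \item{ground_truth}{list with `biomarker_ids`, `severity_driver_ids`,
#'       the latent severity values, and per-score clipping fractions.}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  p <- config$p_pea + config$p_ms + config$p_clin
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  feat_id <- c(sprintf("PEA_%04d", seq_len(config$p_pea)),
               sprintf("MS_%04d", seq_len(config$p_ms)),
               sprintf("CLIN_%03d", seq_len(config$p_clin)))
  platform <- rep(c("PEA", "MS", "CLIN"),
                  c(config$p_pea, config$p_ms, config$p_clin))

  x <- block_gaussian(n, p, config$block_corr, config$block_size)
  block_of <- attr(x, "block_of")
  dimnames(x) <- list(sample_id, feat_id)

  # plant biomarkers in distinct blocks on the proteomic panels; severity
  # drivers are distinct features (block-unconstrained) from the remainder
  prot_idx <- which(platform != "CLIN")
  blocks_avail <- unique(block_of[prot_idx])
  if (length(blocks_avail) < config$n_biomarkers)
    stop("not enough feature blocks to plant biomarkers in distinct blocks; ",
         "increase panel sizes or decrease block_size")
  picked_blocks <- sample(blocks_avail, config$n_biomarkers)
  bm_idx <- vapply(picked_blocks, function(b) {
    cand <- prot_idx[block_of[prot_idx] == b]
    cand[sample.int(length(cand), 1L)]
  }, 1L)
  drv_idx <- sample(setdiff(prot_idx, bm_idx), config$n_severity_drivers)
  is_case <- group == "case"
  x[is_case, bm_idx] <- x[is_case, bm_idx] + config$effect_size

  # latent severity of cases = standardized mean of the driver features
  drv <- x[is_case, drv_idx, drop = FALSE]
  latent <- rowMeans(scale(drv))
  latent <- as.numeric(scale(latent))

  mk <- function(direction, center, spread, lo, hi) {
    u0 <- direction * latent + config$noise_sd * stats::rnorm(sum(is_case))
    bounded_score(u0 / sqrt(1 + config$noise_sd^2), center, spread, lo, hi)
  }
  physical   <- mk(+1, 56, 18, 0, 112)
  capability <- mk(-1, 7.5, 2.1, 1, 14)
  cgi        <- mk(+1, 20.5, 4.8, 6, 35)
  vabs       <- mk(-1, 100, 15, -Inf, Inf)
  viq        <- mk(-1, 100, 15, -Inf, Inf)
  severity <- data.frame(sample_id = sample_id[is_case],
                         physical = physical$value,
                         capability = capability$value,
                         cgi = cgi$value,
                         vabs = vabs$value,
                         viq = viq$value,
                         stringsAsFactors = FALSE)

  # platform assignment (Table-1 style): all remaining cases PEA-only;
  # controls split both / MS-only / PEA-only
  has_pea <- rep(TRUE, n)
  has_ms <- rep(FALSE, n)
  case_rows <- which(is_case); ctrl_rows <- which(!is_case)
  has_ms[case_rows[seq_len(config$n_both_case)]] <- TRUE
  has_ms[ctrl_rows[seq_len(config$n_both_control)]] <- TRUE
  if (config$n_ms_only_control > 0L) {
    ms_only <- ctrl_rows[config$n_both_control + seq_len(config$n_ms_only_control)]
    has_ms[ms_only] <- TRUE
    has_pea[ms_only] <- FALSE
  }
  if (config$layout == "merged") {
    x[!has_pea, platform == "PEA"] <- NA_real_
    x[!has_ms, platform == "MS"] <- NA_real_
    x[!is_case, platform == "CLIN"] <- NA_real_
  }

  labels <- data.frame(sample_id = sample_id, group = group,
                       has_pea = has_pea, has_ms = has_ms,
                       stringsAsFactors = FALSE)
  ground_truth <- list(
    biomarker_ids = feat_id[bm_idx],
    severity_driver_ids = feat_id[drv_idx],
    latent_severity = stats::setNames(latent, sample_id[is_case]),
    clipped_fraction = c(physical = physical$clipped,
                         capability = capability$clipped,
                         cgi = cgi$clipped, vabs = 0, viq = 0),
    feature_platform = stats::setNames(platform, feat_id),
    feature_block = stats::setNames(block_of, feat_id))
  structure(list(features = x, labels = labels, severity = severity,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_cohort")
}

#' Extract the classification subset of a synthetic cohort
#'
#' Proteomic features for all samples, with the case/control label.
#' @param cohort a `"synthetic_cohort"`.
#' @return list with `x` (matrix) and `y` (factor, levels control/case).
#' @export
classification_subset <- function(cohort) {
  keep <- cohort$ground_truth$feature_platform[colnames(cohort$features)] != "CLIN"
  list(x = cohort$features[, keep, drop = FALSE],
       y = factor(cohort$labels$group, levels = c("control", "case")))
}

#' Extract the severity subset of a synthetic cohort
#'
#' All features for case samples plus the five severity scores.
#' @param cohort a `"synthetic_cohort"`.
#' @return list with `x` (matrix, cases only) and `scores` (matrix of the five
#'   severity scores).
#' @export
severity_subset <- function(cohort) {
  cases <- cohort$labels$sample_id[cohort$labels$group == "case"]
  sc <- as.matrix(cohort$severity[, c("physical", "capability", "cgi",
                                      "vabs", "viq")])
  rownames(sc) <- cohort$severity$sample_id
  list(x = cohort$features[cases, , drop = FALSE],
       scores = sc[cases, , drop = FALSE])
}

#' Mask observed cells of a feature matrix
#'
#' Introduces pseudo-missing values for imputation benchmarking: exactly
#' `round(fraction * n_observed)` observed cells are set to `NA`. Under MCAR
#' the cells are drawn uniformly; under MAR the per-row masking weight depends
#' on an observed covariate column (which itself is never masked), so that
#' rows in higher covariate quartiles lose more cells.
#'
#' @param m numeric matrix (may already contain `NA`s; only observed cells are
#'   eligible).
#' @param fraction proportion of observed cells to mask, in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param mar_covariate column index or name driving MAR masking (default: the
#'   first column).
#' @param mar_weights masking weights for the four covariate quartiles
#'   (low to high).
#' @param seed integer seed.
#' @return list with `data` (masked matrix) and `mask` (logical matrix, `TRUE`
#'   at newly masked cells).
#' @export
inject_missingness <- function(m, fraction, mechanism = c("MCAR", "MAR"),
                               mar_covariate = 1L,
                               mar_weights = c(0.2, 0.4, 0.6, 0.8),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  m <- as.matrix(m)
  set.seed(seed)
  obs <- which(!is.na(m))
  mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  n_mask <- round(fraction * length(obs))
  if (n_mask == 0L) return(list(data = m, mask = mask))
  if (mechanism == "MCAR") {
    hit <- sample(obs, n_mask)
  } else {
    cov_col <- if (is.character(mar_covariate)) match(mar_covariate, colnames(m))
               else as.integer(mar_covariate)
    if (is.na(cov_col) || cov_col < 1L || cov_col > ncol(m))
      stop("mar_covariate does not identify a column")
    cv <- m[, cov_col]
    if (anyNA(cv)) stop("MAR covariate column must be fully observed")
    q <- stats::quantile(cv, probs = c(0.25, 0.5, 0.75))
    quart <- findInterval(cv, q) + 1L  # 1..4
    w_row <- mar_weights[quart]
    eligible <- obs[((obs - 1L) %/% nrow(m) + 1L) != cov_col]
    w <- w_row[(eligible - 1L) %% nrow(m) + 1L]
    n_mask <- min(n_mask, length(eligible))
    hit <- sample(eligible, n_mask, prob = w)
  }
  mask[hit] <- TRUE
  m[hit] <- NA_real_
  list(data = m, mask = mask)
}

#' Simulate a PPI graph with planted hub proteins
#'
#' Background nodes form a sparse Erdos-Renyi graph; each hub is wired into a
#' dense clique of dedicated members and attached to a large fraction of the
#' background, so hubs dominate degree, betweenness, closeness, MCC and DMNC.
#' STRING-style confidence scores (700-1000) are attached to every edge.
#'
#' @param n_background number of background nodes.
#' @param n_hubs number of planted hubs (>= 1).
#' @param p_edge background edge probability.
#' @param hub_attach_frac fraction of background nodes each hub attaches to.
#' @param clique_size size of each hub's clique (hub + dedicated members).
#' @param hub_names,background_names optional node names; defaults are
#'   `HUB1..` and `BG001..`.
#' @param seed integer seed.
#' @return list with `graph` (igraph, undirected, edge attribute
#'   `combined_score`) and `ground_truth` (`hub_ids`).
#' @export
simulate_ppi <- function(n_background = 100L, n_hubs = 3L, p_edge = 0.05,
                         hub_attach_frac = 0.4, clique_size = 6L,
                         hub_names = NULL, background_names = NULL,
                         seed = 1L) {
  if (n_hubs < 1L) stop("n_hubs must be >= 1")
  set.seed(seed)
  bg <- if (is.null(background_names)) sprintf("BG%03d", seq_len(n_background))
        else background_names
  if (length(bg) != n_background) stop("background_names length mismatch")
  hubs <- if (is.null(hub_names)) sprintf("HUB%d", seq_len(n_hubs)) else hub_names
  if (length(hubs) != n_hubs) stop("hub_names length mismatch")
  edges <- list()
  if (n_background >= 2L && p_edge > 0) {
    pair <- utils::combn(bg, 2L)
    keep <- stats::runif(ncol(pair)) < p_edge
    if (any(keep)) edges[[length(edges) + 1L]] <-
      cbind(pair[1L, keep], pair[2L, keep])
  }
  clique_members <- character(0)
  for (h in seq_len(n_hubs)) {
    mem <- sprintf("%s_C%d", hubs[h], seq_len(clique_size - 1L))
    clique_members <- c(clique_members, mem)
    nodes_h <- c(hubs[h], mem)
    pair <- utils::combn(nodes_h, 2L)
    edges[[length(edges) + 1L]] <- t(pair)
    n_att <- ceiling(hub_attach_frac * n_background)
    att <- sample(bg, n_att)
    edges[[length(edges) + 1L]] <- cbind(hubs[h], att)
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1L], to = em[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c(hubs, clique_members, bg),
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  igraph::E(g)$combined_score <- round(stats::runif(igraph::ecount(g), 700, 1000))
  list(graph = g, ground_truth = list(hub_ids = hubs))
}

#' Simulate an external expression set with known per-gene AUROC
#'
#' Each gene's expression is Gaussian with unit variance; cases are shifted by
#' `shifts[g]` standard deviations, so the expected AUROC of gene `g` is
#' `pnorm(shifts[g] / sqrt(2))`. Cases optionally carry progression-group
#' labels (slow / average / rapid) and per-gene progression slopes that add
#' `slope * (0, 1, 2)` to the three groups, emulating progression-dependent
#' expression.
#'
#' @param n_case,n_control samples per group.
#' @param genes character vector of gene ids.
#' @param shifts numeric vector (recycled) of case-vs-control shifts in SD
#'   units, one per gene.
#' @param progression_slopes optional per-gene slope across progression groups
#'   (default 0).
#' @param seed integer seed.
#' @return list with `expr` (gene x sample matrix), `phenotype` (data frame
#'   with `sample_id`, `phenotype`, `progression`) and `ground_truth`
#'   (`auroc_expected` per gene).
#' @export
simulate_expression <- function(n_case = 8L, n_control = 7L, genes,
                                shifts = 0, progression_slopes = 0,
                                seed = 1L) {
  set.seed(seed)
  genes <- as.character(genes)
  shifts <- rep_len(shifts, length(genes))
  slopes <- rep_len(progression_slopes, length(genes))
  n <- n_case + n_control
  ids <- c(sprintf("CASE%03d", seq_len(n_case)),
           sprintf("CTRL%03d", seq_len(n_control)))
  prog <- rep(c("slow", "average", "rapid"), length.out = n_case)
  prog_level <- match(prog, c("slow", "average", "rapid")) - 1L
  expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, ids))
  expr[, seq_len(n_case)] <- expr[, seq_len(n_case)] + shifts +
    outer(slopes, prog_level)
  phenotype <- data.frame(
    sample_id = ids,
    phenotype = rep(c("case", "control"), c(n_case, n_control)),
    progression = c(prog, rep(NA_character_, n_control)),
    stringsAsFactors = FALSE)
  list(expr = expr, phenotype = phenotype,
       ground_truth = list(auroc_expected =
                             stats::setNames(stats::pnorm(shifts / sqrt(2)),
                                             genes)))
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `features.tsv` (samples as rows, `sample_id` first column, empty cell
#' = missing), `labels.tsv`, `severity.tsv` and `ground_truth.json`.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("features.tsv", "labels.tsv", "severity.tsv",
                            "ground_truth.json"))
  feat <- data.frame(sample_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(feat, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(cohort$labels, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$severity, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- cohort$ground_truth
  gt$latent_severity <- as.list(gt$latent_severity)
  gt$feature_platform <- NULL  # large and reconstructable from column names
  gt$feature_block <- NULL
  jsonlite::write_json(gt, paths[4L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
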
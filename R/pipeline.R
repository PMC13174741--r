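#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], populated for a
#' self-contained synthetic demonstration: a correlated two-panel cohort with
#' ten planted biomarkers, an imputation benchmark per subset, both model
#' banks, stability + minimal-depth selection, block-derived gene sets for
#' enrichment, a PPI with the planted biomarkers wired as hubs, and an
#' external expression set for per-gene AUROC corroboration. Every stage
#' draws its seed deterministically from the global `seed`.
#'
#' @param seed global integer seed.
#' @return a nested list; override entries and pass to [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_case = 40L, n_control = 40L, p_pea = 120L, p_ms = 120L,
                  p_clin = 15L, n_biomarkers = 10L, effect_size = 1.5,
                  n_severity_drivers = 5L, noise_sd = 1.0, block_corr = 0.3,
                  layout = "complete"),
    impute = list(enabled = TRUE, fraction = 0.1, M = 3L,
                  methods = c("mean", "iterative_pca", "soft_svd",
                              "forest", "hot_deck"),
                  ntree = 30L, max_cycles = 2L),
    models = list(enabled = TRUE, train_frac = 0.7),
    select = list(alpha_grid = seq(0.1, 1, by = 0.1), B_stability = 200L,
                  stability_threshold = 0.8, B_depth = 20L,
                  depth_ntree = 100L, z_threshold = 2),
    enrich = list(enabled = TRUE, gmt = "auto", p_adj_max = 0.01,
                  fold_min = 1.5),
    netrank = list(top_k = 20L, min_score = 700, p_edge = 0.05,
                   hub_attach_frac = 0.4, clique_size = 6L),
    validate = list(n_case = 8L, n_control = 7L, shift_biomarker = 2.0,
                    auroc_min = 0.8, top_n = 6L)
  )
}

pipeline_log <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: synthetic cohort generation; per-subset imputation
#' benchmarking (and application of the selected imputer when the subset has
#' missing cells); the classification and severity model banks; stability and
#' minimal-depth feature selection with candidate merging; optional
#' over-representation analysis; PPI centrality consensus ranking; and
#' per-gene AUROC corroboration of the final candidates on a simulated
#' external expression set. Each stage writes TSV/JSON artifacts into
#' `out_dir` and is recorded, with its parameters and output-file hashes, in
#' `manifest.json`. Runs with the same configuration are byte-identical.
#'
#' @param config a list from [pipeline_config()] (possibly with overrides),
#'   or the path to a YAML file holding such overrides.
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the run directory, the manifest, and the
#'   main in-memory results (cohort, reports, profiles, ranking, validation).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(params = params, outputs = basename(files))
    outputs <<- c(outputs, files)
    pipeline_log(log_path, "stage ", stage, ": ", length(files), " artifact(s)")
  }
  seed <- config$seed

  ## 1. synthetic cohort -----------------------------------------------
  cc <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
  cohort <- simulate_cohort(cc)
  files <- write_cohort(cohort, out_dir)
  note("synth", config$cohort, files)
  cls <- classification_subset(cohort)
  sev <- severity_subset(cohort)

  ## 2. imputation benchmark per subset --------------------------------
  impute_reports <- list()
  if (isTRUE(config$impute$enabled)) {
    for (sub in c("classification", "severity")) {
      m <- if (sub == "classification") cls$x else sev$x
      complete_cols <- colSums(is.na(m)) == 0L
      mc <- m[, complete_cols, drop = FALSE]
      mc <- mc[stats::complete.cases(mc), , drop = FALSE]
      rep <- benchmark_imputation(
        mc, fraction = config$impute$fraction,
        methods = config$impute$methods, M = config$impute$M,
        seed = seed + 1L, ntree = config$impute$ntree,
        max_cycles = config$impute$max_cycles)
      impute_reports[[sub]] <- rep
      f <- tsv_out(cbind(subset = sub, rep),
                   file.path(out_dir, paste0("impute_report_", sub, ".tsv")))
      sel <- rep$method[rep$selected]
      jsonlite::write_json(list(subset = sub, selected = sel),
                           file.path(out_dir,
                                     paste0("impute_selected_", sub, ".json")),
                           auto_unbox = TRUE)
      note(paste0("impute_", sub),
           config$impute[c("fraction", "M", "methods")],
           c(f, file.path(out_dir, paste0("impute_selected_", sub, ".json"))))
      # apply the selected imputer where the subset itself has holes
      if (anyNA(m)) {
        filled <- impute_matrix(m, sel, ntree = config$impute$ntree,
                                max_cycles = config$impute$max_cycles,
                                seed = seed + 2L)
        if (sub == "classification") cls$x <- filled else sev$x <- filled
        pipeline_log(log_path, "applied ", sel, " imputation to the ",
                     sub, " subset")
      }
    }
  } else pipeline_log(log_path, "stage impute: skipped (disabled)")

  ## 3. model banks -----------------------------------------------------
  class_report <- severity_report <- NULL
  if (isTRUE(config$models$enabled)) {
    sp <- stratified_split(cls$y, config$models$train_frac, seed = seed + 3L)
    zs <- zscore_fit_apply(cls$x[sp$train, , drop = FALSE],
                           cls$x[sp$test, , drop = FALSE])
    class_report <- train_eval_classifiers(zs$train, cls$y[sp$train],
                                           zs$test, cls$y[sp$test],
                                           seed = seed + 4L)
    f1 <- tsv_out(class_report, file.path(out_dir, "classification_report.tsv"))

    n_sev <- nrow(sev$x)
    tr_idx <- sort(sample.int(n_sev, round(config$models$train_frac * n_sev)))
    te_idx <- setdiff(seq_len(n_sev), tr_idx)
    zs2 <- zscore_fit_apply(sev$x[tr_idx, , drop = FALSE],
                            sev$x[te_idx, , drop = FALSE])
    severity_bank <- train_eval_severity(zs2$train,
                                         sev$scores[tr_idx, , drop = FALSE],
                                         zs2$test,
                                         sev$scores[te_idx, , drop = FALSE],
                                         seed = seed + 5L)
    severity_report <- severity_bank$report
    f2 <- tsv_out(severity_report, file.path(out_dir, "severity_report.tsv"))
    f3 <- tsv_out(severity_bank$per_score,
                  file.path(out_dir, "severity_per_score.tsv"))
    note("models", config$models, c(f1, f2, f3))
  } else pipeline_log(log_path, "stage models: skipped (disabled)")

  ## 4. feature selection ----------------------------------------------
  zs_all <- zscore_fit_apply(cls$x)$train
  alpha_star <- tune_penalty_mixing(zs_all, cls$y,
                                    grid = config$select$alpha_grid,
                                    seed = seed + 6L)
  stab <- stability_select(zs_all, cls$y, alpha_star,
                           B = config$select$B_stability,
                           threshold = config$select$stability_threshold,
                           seed = seed + 7L)
  depth <- depth_select(zscore_fit_apply(sev$x)$train, sev$scores,
                        B = config$select$B_depth,
                        z_threshold = config$select$z_threshold,
                        ntree = config$select$depth_ntree, seed = seed + 8L)
  candidates <- merge_candidates(stab$retained, depth$retained)
  f_stab <- tsv_out(data.frame(feature = names(stab$frequency),
                               frequency = stab$frequency,
                               retained = names(stab$frequency) %in%
                                 stab$retained),
                    file.path(out_dir, "stability_frequencies.tsv"))
  f_depth <- tsv_out(data.frame(feature = rownames(depth$importance_z),
                                depth$importance_z,
                                retained = rownames(depth$importance_z) %in%
                                  depth$retained, check.names = FALSE),
                     file.path(out_dir, "depth_importance.tsv"))
  f_cand <- tsv_out(candidates, file.path(out_dir, "candidates.tsv"))
  note("select",
       c(config$select, list(alpha_star = as.numeric(alpha_star))),
       c(f_stab, f_depth, f_cand))

  ## 5. enrichment (optional) ------------------------------------------
  enrich_tabs <- NULL
  if (isTRUE(config$enrich$enabled) && nrow(candidates) > 0L) {
    collection <-
      if (identical(config$enrich$gmt, "auto")) {
        blocks <- cohort$ground_truth$feature_block
        prot <- names(blocks)[cohort$ground_truth$feature_platform != "CLIN"]
        split(prot, paste0("BLOCK_", blocks[prot]))
      } else read_gmt(config$enrich$gmt)
    background <- colnames(cls$x)
    strata <- stratify_by_direction(cls$x, cls$y,
                                    intersect(candidates$feature, background))
    enrich_tabs <- list()
    for (dir_tag in c("up", "down")) {
      q <- strata[[dir_tag]]
      if (!length(q)) next
      tab <- ora_test(q, background, collection)
      tab <- filter_terms(tab, config$enrich$p_adj_max, config$enrich$fold_min)
      enrich_tabs[[dir_tag]] <- tab
    }
    f <- character(0)
    for (dir_tag in names(enrich_tabs))
      f <- c(f, tsv_out(enrich_tabs[[dir_tag]],
                        file.path(out_dir,
                                  paste0("enrichment_", dir_tag, ".tsv"))))
    note("enrich", config$enrich[c("p_adj_max", "fold_min")], f)
  } else pipeline_log(log_path,
                      "stage enrich: skipped (disabled or no candidates)")

  ## 6. PPI consensus ranking ------------------------------------------
  planted <- cohort$ground_truth$biomarker_ids
  hub_ids <- intersect(planted, candidates$feature)
  bg_ids <- setdiff(candidates$feature, hub_ids)
  if (length(bg_ids) < 5L)  # pad so the background graph is non-trivial
    bg_ids <- c(bg_ids, sprintf("PAD_%03d", seq_len(5L - length(bg_ids))))
  ranking <- NULL
  if (length(hub_ids) >= 1L) {
    ppi <- simulate_ppi(n_background = length(bg_ids),
                        n_hubs = length(hub_ids),
                        p_edge = config$netrank$p_edge,
                        hub_attach_frac = config$netrank$hub_attach_frac,
                        clique_size = config$netrank$clique_size,
                        hub_names = hub_ids, background_names = bg_ids,
                        seed = seed + 9L)
    ranking <- consensus_rank(ppi$graph, top_k = config$netrank$top_k)
    sub <- cc_subnetwork(ppi$graph, top_k = min(config$netrank$top_k,
                                                igraph::vcount(ppi$graph)))
    f <- write_netrank(ranking, sub, out_dir)
    note("netrank", config$netrank, f)
  } else pipeline_log(log_path,
                      "stage netrank: skipped (no planted hub was selected)")

  ## 7. external corroboration -----------------------------------------
  validation <- NULL
  if (!is.null(ranking)) {
    top <- ranking$top
    shifts <- ifelse(top %in% planted, config$validate$shift_biomarker, 0)
    ext <- simulate_expression(config$validate$n_case,
                               config$validate$n_control,
                               genes = top, shifts = shifts,
                               seed = seed + 10L)
    eset <- list(expr = ext$expr,
                 phenotype = factor(ext$phenotype$phenotype,
                                    levels = c("control", "case")),
                 progression = ext$phenotype$progression)
    validation <- rank_candidates(eset, top,
                                  auroc_min = config$validate$auroc_min,
                                  top_n = config$validate$top_n)
    f <- tsv_out(validation$table, file.path(out_dir, "validation_roc.tsv"))
    note("validate", config$validate, f)
  } else pipeline_log(log_path, "stage validate: skipped (no ranking)")

  ## manifest ------------------------------------------------------------
  hashes <- tools::md5sum(outputs)
  manifest$files <- stats::setNames(as.list(unname(hashes)), basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest, cohort = cohort,
                 impute_reports = impute_reports,
                 classification_report = class_report,
                 severity_report = severity_report,
                 alpha_star = as.numeric(alpha_star),
                 stability = stab, depth = depth, candidates = candidates,
                 enrichment = enrich_tabs, ranking = ranking,
                 validation = validation))
}
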
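test_that("cohort dimensions, labels and determinism follow the configuration", {
  cfg <- cohort_config(n_case = 28, n_control = 30, p_pea = 100, p_ms = 50,
                       p_clin = 10, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$features), c(58, 160))
  expect_equal(sum(co$labels$group == "case"), 28)
  expect_equal(nrow(co$severity), 28)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$features, co2$features)
  expect_identical(co$severity, co2$severity)

  expect_error(cohort_config(n_case = 0), "count")
  expect_error(cohort_config(p_pea = 5, p_ms = 5, n_biomarkers = 11),
               "exceeds")
  expect_error(cohort_config(block_corr = 1), "block_corr")
})

test_that("merged layout reproduces the two-platform missingness structure", {
  co <- simulate_cohort(cohort_config(n_case = 28, n_control = 30,
                                      p_pea = 40, p_ms = 40, p_clin = 5,
                                      n_biomarkers = 5, n_severity_drivers = 3,
                                      layout = "merged", seed = 1))
  plat <- co$ground_truth$feature_platform[colnames(co$features)]
  pea_measured <- rowSums(!is.na(co$features[, plat == "PEA"])) > 0
  ms_measured <- rowSums(!is.na(co$features[, plat == "MS"])) > 0
  expect_equal(sum(pea_measured), 58 - 15)       # 15 MS-only controls
  expect_equal(sum(ms_measured), 20 + 10 + 15)   # both cases+controls, MS-only
  # clinical features exist for cases only
  clin_measured <- rowSums(!is.na(co$features[, plat == "CLIN"])) > 0
  expect_equal(sum(clin_measured), 28)
})

test_that("severity scores stay in range and track the latent severity", {
  co <- simulate_cohort(cohort_config(n_case = 200, n_control = 10,
                                      p_pea = 40, p_ms = 40, p_clin = 5,
                                      n_biomarkers = 5, n_severity_drivers = 3,
                                      layout = "complete", seed = 11))
  s <- co$severity
  expect_true(all(s$physical >= 0 & s$physical <= 112))
  expect_true(all(s$capability >= 1 & s$capability <= 14))
  expect_true(all(s$cgi >= 6 & s$cgi <= 35))
  lat <- co$ground_truth$latent_severity
  expect_gt(cor(s$physical, lat), 0)
  expect_gt(cor(s$cgi, lat), 0)
  expect_lt(cor(s$capability, lat), 0)
  expect_lt(cor(s$vabs, lat), 0)
  expect_lt(cor(s$viq, lat), 0)
})

test_that("planted effect size is recovered empirically and vanishes at zero", {
  co <- simulate_cohort(cohort_config(n_case = 2000, n_control = 2000,
                                      p_pea = 15, p_ms = 15, p_clin = 2,
                                      n_biomarkers = 4, effect_size = 1.0,
                                      n_severity_drivers = 2, block_size = 5,
                                      layout = "complete", seed = 21))
  is_case <- co$labels$group == "case"
  for (b in co$ground_truth$biomarker_ids) {
    v <- co$features[, b]
    d <- (mean(v[is_case]) - mean(v[!is_case])) /
      sqrt((stats::var(v[is_case]) + stats::var(v[!is_case])) / 2)
    expect_lt(abs(d - 1.0), 0.1)
  }
  co0 <- simulate_cohort(cohort_config(n_case = 500, n_control = 500,
                                       p_pea = 15, p_ms = 15, p_clin = 2,
                                       n_biomarkers = 4, effect_size = 0,
                                       n_severity_drivers = 2, block_size = 5,
                                       layout = "complete", seed = 22))
  isc <- co0$labels$group == "case"
  for (b in co0$ground_truth$biomarker_ids) {
    tt <- t.test(co0$features[isc, b], co0$features[!isc, b])
    expect_lt(abs(tt$statistic), 4)
  }
})

test_that("missingness injection masks exactly the requested cells", {
  m <- matrix(rnorm(1000), 100, 10)
  out <- inject_missingness(m, 0.10, "MCAR", seed = 1)
  expect_equal(sum(out$mask), 100)
  expect_equal(sum(is.na(out$data)), 100)
  expect_identical(out$data[!out$mask], m[!out$mask])

  id <- inject_missingness(m, 0, seed = 1)
  expect_identical(id$data, m)
  expect_equal(sum(id$mask), 0)
  expect_error(inject_missingness(m, 1), "fraction")

  # masking only touches observed cells
  m2 <- m; m2[1:20, 1] <- NA
  out2 <- inject_missingness(m2, 0.1, seed = 2)
  expect_false(any(out2$mask & is.na(m2)))
  expect_equal(sum(out2$mask), round(0.1 * sum(!is.na(m2))))
})

test_that("MAR masking skews masked cells toward high covariate quartiles", {
  set.seed(9)
  m <- matrix(rnorm(500 * 81), 500, 81)
  frac <- 10000 / sum(!is.na(m))
  out <- inject_missingness(m, frac, "MAR", mar_covariate = 1, seed = 4)
  cv <- m[, 1]
  quart <- findInterval(cv, quantile(cv, c(.25, .5, .75))) + 1
  counts <- tabulate(quart[row(m)[out$mask]], 4)
  expect_lt(chisq.test(counts)$p.value, 0.01)
  expect_true(all(diff(counts) > 0))       # monotone in the weights
  expect_false(any(out$mask[, 1]))         # covariate column never masked
})

test_that("simulated PPI hubs dominate by construction", {
  pp <- simulate_ppi(n_background = 100, n_hubs = 3, seed = 5)
  deg <- igraph::degree(pp$graph)
  top3 <- names(sort(deg, decreasing = TRUE))[1:3]
  expect_setequal(top3, pp$ground_truth$hub_ids)
  pp2 <- simulate_ppi(n_background = 100, n_hubs = 3, seed = 5)
  expect_identical(igraph::as_data_frame(pp$graph),
                   igraph::as_data_frame(pp2$graph))
  # single hub over an edgeless background: unique consensus maximum
  star <- simulate_ppi(n_background = 20, n_hubs = 1, p_edge = 0, seed = 2)
  r <- consensus_rank(star$graph, top_k = 5)
  expect_identical(r$table$node[1], "HUB1")
  expect_gt(r$table$consensus[1], max(r$table$consensus[-1]))
})

test_that("simulated expression matches the closed-form AUROC and is reproducible", {
  ex <- simulate_expression(200, 200, genes = c("null", "strong"),
                            shifts = c(0, 2), seed = 13)
  expect_identical(ex$expr,
                   simulate_expression(200, 200, c("null", "strong"),
                                       c(0, 2), seed = 13)$expr)
  expect_equal(unname(ex$ground_truth$auroc_expected["strong"]),
               pnorm(2 / sqrt(2)))
  pos <- ex$phenotype$phenotype == "case"
  a_null <- oracle_auroc(ex$expr["null", ], pos)
  expect_lt(abs(a_null - 0.5), 0.08)
})
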
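---
title: "Biomarker discovery for rare-disease proteomic cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker discovery for rare-disease proteomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rare neurodegenerative diseases such as CLN3 disease (juvenile neuronal
ceroid lipofuscinosis) need objective fluid biomarkers for early diagnosis,
progression tracking, and trial endpoints. The cohorts available for
discovery are small (tens of participants), assayed on heterogeneous
platforms — an antibody-based PEA panel on some samples, mass-spectrometry
proteomics on a partially overlapping subset, plus clinical measurements —
and carry substantial missingness. `proteoscout` implements a complete
discovery chain for this setting:

1. **Imputation benchmarking** — choose a completion method per data subset
   by masking observed cells and scoring recovery.
2. **Model banks** — a five-classifier bank for case/control discrimination
   and a six-model multi-output bank predicting five disease-severity scores.
3. **Resampling-based feature selection** — bootstrapped penalized-logistic
   stability selection on the classification side; random-forest mean
   minimal depth on the severity side.
4. **Over-representation analysis** of the merged candidates against GMT
   gene sets.
5. **PPI consensus hub ranking** — five centrality measures (degree,
   betweenness, closeness, maximal clique centrality, DMNC), min–max
   normalized and averaged; the top 20 nodes become the candidate set.
6. **External corroboration** — per-gene AUROC of candidates on an
   independent case/control expression matrix.

A synthetic cohort generator with planted ground truth makes every stage
testable without access to clinical data; it is first-class, tested code,
not a fixture.

# The synthetic cohort generator

`simulate_cohort()` draws features from exchangeable-correlation Gaussian
blocks (block size 10, within-block correlation `block_corr`; marginal SD 1),
so panels have realistic correlated structure without estimating a covariance
from real data. Planted biomarkers are shifted by `effect_size` (Cohen's *d*
units) in cases, each placed in a distinct block so that recovering one does
not trivially recover another. A latent severity variable for cases is the
standardized mean of designated driver features; the five severity scores
are affine maps of this latent (plus Gaussian noise of SD `noise_sd` on the
latent scale) into the instruments' published ranges, clipped at the edges
with the clipped fraction logged:

| score       | range      | direction vs. severity |
|-------------|-----------|------------------------|
| Physical    | 0–112     | increases              |
| Capability  | 1–14      | decreases              |
| CGI         | 6–35      | increases              |
| VABS        | mean 100, SD 15 | decreases        |
| VIQ         | mean 100, SD 15 | decreases        |

The default configuration mirrors the structure of the motivating study:
28 cases and 30 controls on a 1,467-protein PEA panel, a 3,319-protein MS
panel covering 20 cases and 25 controls (20 cases and 10 controls on both
platforms, 15 MS-only healthy controls), and 226 clinical features measured
on cases only. The `"merged"` layout emits the union matrix with
platform-block missingness; `"complete"` observes everything.

`inject_missingness()` masks exactly `round(fraction × n_observed)` observed
cells. MCAR draws cells uniformly; MAR weights rows by the quartile of one
designated, never-masked covariate column (default weights 0.2/0.4/0.6/0.8),
the simplest mechanism whose signature — masked cells skewed toward high
covariate quartiles — is directly testable.

What the generator does *not* emulate: Olink NPX distributions,
MS intensity heteroscedasticity, batch effects, or informative (MNAR)
missingness. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal under idealized Gaussian
conditions, not performance on real assay data.

# Imputation benchmarking

Five imputers share one interface (`impute_matrix()`): column means;
EM-style iterative PCA (rank-*k* truncated SVD of the column-centered
matrix, refilling only missing cells; defaults k = 5, tol = 1e-6,
max 1000 iterations); soft-thresholded SVD (nuclear-norm relaxation,
λ defaulting to 0.1 × the largest singular value of the mean-filled matrix;
its objective ½‖P_obs(M−X)‖² + λ‖X‖\* is non-increasing by construction and
asserted in tests); per-column regression forests cycled until the
imputation change stops decreasing; and group-aware hot deck. Observed
cells are never modified — enforced by overwriting the output with the
original observed values.

`evaluate_imputation()` scores an M-replicate ensemble at the masked cells:
with x̂ᵢ the across-replicate mean, MAE, MSE = RMSE², raw bias
RB = mean(xᵢ − x̂ᵢ), and PB = 100·|RB|/|mean(xᵢ)|. The per-cell 95% interval
is x̂ᵢ ± 1.96·sᵢ/√M, where sᵢ is the across-replicate SD: the standard error
of the ensemble-mean imputation, which is the estimator the error metrics
score. This calibrates correctly — a noise ensemble x̂ᵢ⁽ᵐ⁾ = xᵢ + εᵢ⁽ᵐ⁾,
ε ~ N(0,1), covers at ≈ 95% — while a deterministic method yields zero-width
intervals and hence CR = 0 and AW = 0 unless it is exactly right, the
pattern a deterministic SVD imputer shows in practice. (An interval of
x̂ᵢ ± 1.96·sᵢ without the √M would cover the truth with probability → 1,
because the center's error shrinks with M while the halfwidth does not;
it cannot exhibit nominal coverage for any calibrated ensemble.)

`benchmark_imputation()` masks once so all methods face the identical mask,
and flags the lowest-MAE method (RMSE tie-break) as `selected`; the full
report is returned so users can override on secondary criteria (PB, CR, AW).

# Model banks

Features are z-scored with training-set statistics only (population-SD
convention; zero-variance columns map to zero and are flagged), then applied
to the held-out split — fitting the normalization on the full data would
leak test information, so the split-honest version is the default.
`stratified_split()` holds out per-class `round((1−f)·n)` samples.

Classification bank: plain binomial logistic regression; LASSO logistic
regression at the 10-fold-CV-optimal penalty; a 500-tree random forest;
an RBF SVM with Platt probability outputs (C = 1, γ = 1/(p·var), the cited
implementation's defaults); and gradient boosting (binary-logistic
objective, η = 0.1, depth 3, 100 rounds). Metrics: confusion-matrix
summaries at threshold 0.5 plus AUROC by the rank (Mann–Whitney) statistic
with midrank ties; balanced accuracy = (sensitivity + specificity)/2 is an
asserted invariant.

Severity bank (five scores jointly): multivariate linear regression;
5-component PLS; a 500-tree random forest per score (R's forest
implementation has no multivariate-response mode, so the multi-output model
is realized as one forest per score); per-score gradient boosting
(squared-error objective, 100 rounds, η = 0.1, depth 3); the grouped
multi-response LASSO with 5-fold CV; and a feed-forward network with two
hidden ReLU layers (64 and 32 units), linear 5-unit output, squared-error
loss, Adam (lr 1e-3), 100 epochs, batch 16 — implemented natively as a small
matrix backprop routine with seeded initialization. Selection: lowest
average test RMSE, tie-break highest average R². R² may be strongly
negative for models that diverge on small samples (typically the network),
which is informative and reported as-is.

# Feature selection

**Stability selection.** `tune_penalty_mixing()` scans the elastic-net
mixing parameter α over a grid (default 0–1 by 0.1) by 5-fold
cross-validated AUROC with stratified folds shared across the grid; ties go
to the smallest α. Note that α = 0 (ridge) never zeroes a coefficient, so
selection frequencies are degenerate there — the function warns. More
broadly, the prediction-optimal α on high-dimensional data is often
near-ridge, which is antithetical to support recovery; when the goal is a
sparse stable set rather than predictive tuning, running
`stability_select()` at a balanced mixing (α = 0.5) is a sensible default,
and this is what the package's own recovery checks do.
`stability_select()` draws B = 200 bootstrap samples of participants,
re-fits at the fixed α with the penalty strength re-chosen by CV inside
each bootstrap, and retains features with nonzero coefficients in ≥ 80% of
bootstraps. The per-bootstrap penalty defaults to `lambda.1se` — the
strongest penalty within one standard error of the CV optimum — because
`lambda.min` optimizes prediction and admits tens of spurious coefficients
per fit, which inflates the stable false-positive set several-fold on
planted-signal simulations; `lambda_rule = "lambda.min"` restores the
prediction-optimal behavior, and `lambda` freezes the penalty outright.

**Minimal depth.** The minimal depth of feature *f* in a tree is the depth
(root = 0) of the shallowest node splitting on *f*; trees not using *f*
contribute max tree depth + 1, the standard fill-in of tree explainers.
`depth_select()` averages the per-feature mean minimal depth over B = 50
bootstrap forests per severity score, negates it (shallow = influential) and
z-scores within each score — negation is the only orientation under which
"importance z > 2" selects influential features. A feature is retained when
it exceeds the threshold for at least one score (union; an intersection
rule is available via `aggregate = "all"`). Under pure noise the retained
fraction per score approaches the one-sided normal tail beyond 2 (≈ 2.3%),
so the union over five scores carries a ≈ 10% family-wise false rate —
accepted, as the downstream network stage re-filters candidates.

`merge_candidates()` unions the two sets with provenance tags
(classification / severity / both) and stable first-seen ordering.

# Enrichment

`ora_test()` is a hypergeometric upper tail: with a query of n genes from a
background universe of N containing K members of a set, the overlap k is
scored by P(X ≥ k) and the enrichment fold (k/n)/(K/N); p-values are BH
adjusted across sets. Candidates are first stratified into up- and
down-regulated groups by the sign of the case-minus-control mean difference
and each group is analyzed independently. Filters follow the conventional
stringent thresholds as strict inequalities: adjusted p < 0.01 and
fold > 1.5, so rows exactly at either boundary are dropped. The background
defaults to all features measured on the platform, the conservative choice
when the assay panel, not the genome, defines what could have been seen.

# Network consensus ranking

The PPI graph is built from a STRING-style edge list (combined score
0–1000), keeping edges at score ≥ 700 — STRING's named "high confidence"
level — canonicalizing unordered pairs and dropping self-loops; supplied
nodes absent from the edge list are kept as isolates. All centralities are
computed on the unweighted simple graph, as hub-ranking tools conventionally
do:

* **DC** — degree.
* **BC** — betweenness normalized by (n−1)(n−2)/2, so values read as the
  fraction of shortest paths through the node.
* **CC** — Wasserman–Faust closeness ((r−1)/Σd)·((r−1)/(n−1)) over the r
  reachable nodes, which degrades gracefully on disconnected graphs (a
  couple-hundred-node interaction network at high confidence is almost
  never connected); isolates score 0.
* **MCC** — Σ over maximal cliques C containing v of (|C|−1)!, enumerated
  by Bron–Kerbosch with pivoting; in a triangle-free neighborhood this
  reduces to the degree.
* **DMNC** — E/V^1.7 of the largest connected component of the subgraph
  induced by v's neighbors; ties broken by edge count, then by smallest
  member label.

Each metric is min–max normalized across nodes (a constant metric maps to
all zeros, which shifts no ordering, and is flagged); the consensus is the
unweighted mean of the five normalized scores, and nodes are ranked by
descending consensus with ties broken by node id. The closeness-centered
subnetwork collects the top-k CC nodes, their first-degree neighbors, and
every node on at least one shortest path between two top nodes, with roles
tagged hub > interactor > path.

# External corroboration

`gene_auroc()` uses the rank-sum AUROC with midrank ties and reports both
orientations: the directed value (cases above controls) and the
direction-free `max(a, 1−a)` used for ranking, since a biomarker that is
consistently *lower* in cases discriminates equally well. For a gene whose
case values are shifted by d SD against unit-variance noise the expected
AUROC is Φ(d/√2); the generator records this per gene and the empirical
estimate converges to it. `rank_candidates()` sorts by direction-free
AUROC, flags genes strictly above 0.8, and returns the top 6;
`progression_summary()` reports per-group moments (control → slow →
average → rapid) with a strict-monotonicity flag for prognostic patterns.
Probe-to-gene collapse for array data is out of scope: the module consumes
a gene-level expression matrix.

# The pipeline and the demonstration conditions

`run_pipeline()` chains the stages from one configuration (an R list or a
YAML overrides file), writes every stage's TSV/JSON artifacts plus a
manifest with parameters and MD5 hashes, and is byte-identical across runs
with the same seed (all stochastic learners are seeded; boosting runs
single-threaded). Stages lacking inputs are skipped with a logged reason.
In the synthetic demonstration the PPI stage wires the planted biomarkers
that survived feature selection as hubs among the other selected candidates
— so a planted biomarker missed by selection cannot be rescued by the
network stage, and end-to-end recovery is genuinely tested.

The demonstration conditions, chosen once for a desk-scale recovery study:
40 cases / 40 controls, 120 + 120 proteomic features, 15 clinical features,
10 planted biomarkers at d = 1.5, 5 severity drivers, block correlation
0.3, complete layout; imputation benchmark with M = 3 replicates and a
reduced forest (30 trees, 2 cycles); stability selection at the study's
B = 200; depth selection at B = 20 with 100-tree forests. The sample size
and effect are modestly larger than the motivating cohort's 28/30 at
unknown effect size because the demonstration's purpose is to verify that a
planted signal traverses all seven stages, which needs the signal to be
recoverable in principle; the package's separate recovery checks probe the
harder n = 70, p = 300, d = 1.0 regime.

# Numerical choices and degenerate inputs

* Iterative imputers return their last iterate with a warning when the
  iteration cap is hit; all-missing columns are an error naming the column.
* Zero-width intervals (deterministic ensembles) cover only exact equality.
* `stratified_split` snaps floating-point fuzz before rounding per-class
  counts (0.7 × 45 is 31.499999… in double arithmetic, and should round as
  31.5 does).
* Single-class AUROC, folds, or bootstrap draws are errors or redraws
  (bootstraps redraw up to 10 times, logged).
* BH adjustment preserves input order and is monotone over sorted p-values;
  it is a fixed point on constant vectors but not on general monotone
  inputs — no such idempotence is claimed.
* Constant centrality metrics min–max map to zero for all nodes; rankings
  break ties lexicographically so output order is total and reproducible.

# Known limitations

Gaussian, block-exchangeable features are a deliberately simple null for
real proteomics; imputation rankings on real NPX/MS intensities may differ.
The severity bank's network learner routinely overfits at n ≈ 30–40 — this
mirrors experience with small cohorts and is surfaced, not suppressed. The
enrichment stage tests one set at a time against a fixed background and
implements none of the meta-analysis features (term clustering, multi-list
analysis) of web platforms. Centrality consensus weights the five metrics
equally; no claim is made that equal weights are optimal.
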
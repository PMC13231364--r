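---
title: "phenocell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenocell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenocell)
```

This vignette documents the statistical model behind `phenocell`, the
assumptions of its paired-cohort simulator, the parameters that matter,
and the numerical decisions taken where the method left room for choice.

## 1. The selection model

The core object is the correlation design `S` (n bulk samples × m
cells): the Pearson correlation of each bulk sample's and each cell's
log-normalized profile over a common gene universe. A cell whose
transcriptome resembles the bulk samples of phenotype-1 patients more
than those of phenotype-0 patients carries phenotype information, and
`S` makes that legible to a regression: we fit

$$\min_{\beta,\beta_0}\; \frac{1}{n}\,\mathrm{Loss}(y,\ \beta_0 + S\beta)
\;+\; \lambda\Big[\alpha\lVert\beta\rVert_1 +
\frac{1-\alpha}{2}\,\beta^\top L \beta\Big]$$

with the logistic negative log-likelihood for a binary phenotype
(`family = "binomial"`, the default) or half squared error for a
continuous one (e.g. a smoking-dosage covariate; `family = "gaussian"`).
`L` is the normalized Laplacian of a cell–cell similarity graph, so the
quadratic term penalizes coefficient differences between transcriptionally
similar cells: whole cell states move in and out of the selection
together rather than isolated cells. Cells with positive fitted
coefficients form the phenotype-positive set, negative coefficients the
phenotype-negative set, zeros the background.

Assumptions worth stating explicitly:

* bulk expression is approximately a mixture of the cell states present
  in the single-cell compartment, so bulk–cell correlations are
  informative;
* the phenotype associates with the *abundance and expression program* of
  some cell states, not with genes absent from the shared universe;
* Pearson correlation on log-normalized data is an adequate similarity —
  rank-based alternatives are not offered.

### Standardization

Columns of `S` are standardized (mean 0, unit variance across bulk
samples) before regression so that `λ` acts uniformly across cells;
this is standard penalized-regression practice. Cells whose correlation
profile is constant across samples carry no signal and are zeroed rather
than rejected. The raw correlations are kept in the
`correlation_design` object (`$raw`) for inspection.

### The cell graph

The method only requires *some* cell–cell similarity graph. The default
construction: embed cells in the top 30 principal directions of the
log-normalized matrix, connect each cell to its k = 10 nearest
neighbours (Euclidean, ties broken by cell index), symmetrize by union,
binary weights. The normalized Laplacian is
$L = I - D^{-1/2} A D^{-1/2}$ with rows of isolated vertices set to
zero, so an isolated cell is penalized by the L1 term alone. A graph
built from the correlation design itself (cells embedded by their
bulk-correlation profiles) is supported as an alternative input.

### Tuning λ and α

For fixed `α`, `λ` is chosen by stratified K-fold cross-validation
(K = 10) over a 50-point grid log-spaced from `λ_max` (the smallest `λ`
with an all-zero solution, computed from the null-model gradient) down
to `0.01·λ_max`, minimizing mean held-out binomial deviance (or MSE);
exact ties resolve to the larger, sparser `λ`. `α` is then searched over
an ascending grid, 0.05 to 0.90 in steps of 0.05, accepting the first
value whose selected-cell fraction is below the 20% cutoff; if none
qualifies the sparsest solution is returned with a `nonterminated` flag.
The CV fold seed is recorded in the result for reproducibility.

A practical caveat we document rather than hide: on cohorts where many
cells carry weak phenotype signal, the CV deviance curve is nearly flat
over the small-`λ` half of the grid, and the minimum-error rule can
admit weakly informative cells into the selection. Selections at larger
`λ` along the recorded `cv_curve` are markedly purer against planted
ground truth; users who need high precision rather than predictive
optimality should inspect the curve. We keep the minimum-error rule as
the default because it is the stated selection criterion of this
method family.

### The solver

Proximal gradient with FISTA acceleration, backtracking line search, and
monotone restarts; the Laplacian quadratic sits in the smooth part and
the L1 term in the proximal step, the intercept is unpenalized.
Convergence is declared when the relative objective change falls below
`1e-8` (cap 10,000 iterations; non-convergence is an error with
diagnostics, never a silent result). `kkt_residual()` exposes the
maximum subgradient-optimality violation of any returned solution; the
test suite holds toy solutions to ≤ 1e-6 against an independent
coordinate-descent oracle and glmnet.

## 2. The paired-cohort simulator

`generate_paired_dataset()` emulates the study design the method is
built for: a bulk cohort with a binary phenotype (default balance 0.34,
a typical smoker fraction in an East Asian lung-adenocarcinoma cohort),
staged survival outcomes, and a single-cell compartment of discrete cell
types of which one is truly phenotype-positive and one
phenotype-negative.

Generative model, in order:

1. **Gene space.** Relative expression drawn log-normal (σ = 1),
   normalized to sum 1. Unassociated cell types get disjoint 25-gene
   marker blocks (4-fold up). Associated subtypes are distinguished by
   their *program*: 80 genes shifted by `effect_log2fc` (default 1, a
   2-fold change). Programs and markers are disjoint, so the planted
   fold change is exactly `2^effect_log2fc` in expectation.
2. **Cells.** Each cell belongs to a donor (20 donors); a donor's
   cell-type proportions are the baseline (15% for each associated
   subtype) with `enrichment_shift` (default 0.10) added to the
   matching-direction subtype for that donor's phenotype, renormalized.
   Counts are negative-binomial with mean `libsize × profile` (library
   sizes uniform in 2,000–10,000) and dispersion θ = 2, a typical
   single-cell overdispersion.
3. **Bulk.** Per-sample cell-type weights are Dirichlet (concentration
   50 × baseline), shifted by `enrichment_shift` toward the
   matching-direction subtype and renormalized (rows of the ground-truth
   weight matrix sum to 1). Bulk counts are NB around the weighted
   mixture of cell-type mean profiles with θ = 20 (bulk is far less
   overdispersed than single cells).
4. **Survival.** Exponential hazard (Weibull shape fixed at 1) scaled by
   `exp(surv_effect · z)` where `z` is the standardized positive-subtype
   weight; baseline scale 1,000 days, `surv_effect = 1`. Censoring times
   are exponential with the rate matched to a 30% target censor
   fraction. Stage is binary with latent correlation 0.4 to `z`, so the
   Cox stage adjustment is non-trivial.
5. **Determinism.** Everything is drawn from `set.seed(config$seed)`;
   two calls with the same config are bit-identical.

What the simulator does *not* emulate: doublets, ambient RNA, UMI
saturation, batch integration across studies (a two-batch log-normal
gene offset exists but defaults to off), continuous cell-state
gradients, or the composition of any real atlas. Passing tests on this
generator demonstrates that the pipeline recovers planted structure
under its own model assumptions — not that it is robust to the full
messiness of real data.

## 3. Downstream statistics

* **Differential expression** — per-gene two-sided Wilcoxon rank-sum on
  log-normalized values: exact enumeration when both groups have ≤ 10
  tie-free cells, otherwise the tie-corrected normal approximation
  without continuity correction. Fold change is ratio-scale on de-logged
  means with pseudocount 1; genes are tested only if detected in ≥ 10%
  of one group. Significance: |FC| > 1.25 and BH-FDR < 0.05. A gene
  constant across both groups is defined to have p = 1.
* **Preranked GSEA** — weighted Kolmogorov–Smirnov running sum on the
  fold-change ranking (weight exponent 1, ties broken by gene id);
  significance from gene-label permutations (default 1,000), two-tailed
  by ES sign; `NES = ES / mean(|permuted ES|)` over matching-sign
  permutations; BH-FDR across sets; sets kept if 5–500 members after
  filtering to ranked genes. Enriched: P < 0.05 and FDR < 0.25.
* **ssGSEA** — per column, genes ranked descending; the score is the sum
  of (weighted in-set cumulative fraction − uniform out-of-set
  cumulative fraction), weights `rank^tau` with the top gene carrying
  the largest rank value and τ = 0.25. Rank-based, hence invariant to
  monotone transforms of a column. The degenerate whole-universe set
  scores 0 by convention. Min–max normalization across columns is
  off by default (group comparisons are rank-based anyway) and offered
  for cross-cohort bulk scoring.
* **Signature and survival** — the 50 largest-FC significant genes (ties
  by smaller FDR, then gene id); bulk samples scored by ssGSEA and split
  at the median, with median ties assigned to "low" (deterministic).
  Kaplan–Meier product-limit curves and the 1-df log-rank test; Cox
  partial likelihood with Breslow tie handling (Efron available),
  hazard ratio for high vs low with Wald 95% CI, stage entered as a
  binary early/late covariate. Monotone likelihood or non-convergence is
  flagged, never silently reported. Zero events anywhere yields NA for
  the log-rank statistic (curves are still returned).
* **Composition** — per cell type, a 2×2 chi-square without continuity
  correction, switching to Fisher's exact test when any expected count
  is below 5 (the standard rule); BH across types; proportions within
  each selected set. The donor-level alternative regresses per-donor
  proportions on donor phenotype with a dataset covariate by OLS;
  collinear designs (all phenotype-1 donors in one dataset) are flagged
  with no estimate, and an exactly constant response is defined as
  coefficient 0, p 1.

## 4. Open choices and their resolutions

* **Phenotype encoding.** The generator emits a binary phenotype by
  default and optionally a continuous dosage column; the solver's
  gaussian family covers the continuous case. Binary + binomial is the
  default pairing.
* **Correlation gene universe.** Shared highly variable genes by
  default (the `restrict_to` argument of `intersect_genes()`), with all
  common genes available by omitting the restriction. Ribosomal genes
  (RPL/RPS prefixes) can be excluded by flag; the synthetic gene ids are
  neutral so the flag defaults to off.
* **HVG trend.** Standardized variance against a degree-2 polynomial
  fit of log-variance on log-mean — smoother-free and deterministic.
* **One run vs per-compartment runs.** The functions operate on
  whatever cell subset they are given; re-running per compartment is a
  subsetting loop left to the user, as the method itself is agnostic.

## 5. Problem sizes in the test suite

The full-scale configuration (3,000 cells, 1,200 genes, 120 bulk
samples, 10 CV folds) is exercised once in the acceptance tests and in
`scripts/acceptance.R` (about 1–2 minutes). Unit and property tests use
a reduced cohort — 600 cells, 400 genes, 60 bulk samples, 5 folds, 300
HVGs — which preserves every structural feature of the default (five
cell types, both planted directions, survival and stage coupling) at
roughly a tenth of the cost; the null-calibration check runs 20 such
cohorts with no planted effect. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that stays
pleasant to run.

## 6. Known limitations

* Precision of the selected sets depends on where cross-validation
  lands on a flat deviance curve (§1); the recorded `cv_curve` and
  `search` diagnostics exist so users can see this.
* The positive direction is estimated from the minority phenotype class
  (34% balance) and is accordingly noisier than the negative direction.
* Survival simulation is exponential with independent censoring;
  no competing risks, no time-varying effects.
* Gene identifiers are matched as exact strings; no alias resolution.
* The Cox wrapper fits a single binary adjustment covariate (stage);
  richer adjustment sets are out of scope.
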
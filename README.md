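# phenocell

Phenotype-guided selection and characterization of single-cell
subpopulations from bulk RNA-seq cohorts.

## The problem

Bulk RNA-seq cohorts carry clinical phenotypes — smoking status, tumor
stage, survival — but average away cellular heterogeneity; single-cell
RNA-seq resolves cell states but rarely comes with outcome data at cohort
scale. `phenocell` links the two: given a bulk cohort with a binary
phenotype and a single-cell atlas measured over a shared gene space, it
identifies the individual cells whose expression profiles track the
phenotype, then characterizes those subpopulations (differential
expression, gene-set enrichment, gene signatures with survival analysis,
and cell-type composition shifts).

## The method

Let `B` be the bulk matrix (genes × n samples), `C` the single-cell
matrix (genes × m cells), both log-normalized over a common gene universe
(typically the shared highly variable genes). The regression design is
the correlation matrix

    S[i, j] = Pearson(B[, i], C[, j]),        S ∈ R^{n × m},

with columns standardized to mean 0, variance 1 across bulk samples. With
phenotype `y ∈ {0,1}^n` and the normalized Laplacian `L` of a k-nearest-
neighbour cell–cell similarity graph, the per-cell coefficients solve the
network-regularized sparse regression

    min_{β, β0}  (1/n) · Loss(y, β0 + Sβ)
                 + λ [ α‖β‖₁ + ((1−α)/2) · βᵀLβ ],

where `Loss` is the logistic negative log-likelihood (or squared error
for a continuous phenotype). The L1 term selects few cells; the Laplacian
quadratic makes coefficients vary smoothly between similar cells, so
selection respects the cell-state structure. `λ` is chosen by stratified
cross-validation at minimum mean held-out error; `α` is searched over an
ascending grid (0.05–0.90), accepting the first value whose selected-cell
fraction falls below 20%. Cells with `β > 0` form the phenotype-positive
set, `β < 0` the phenotype-negative set; a donor-phenotype
cross-tabulation (chi-square / Fisher) checks that the selection is
concordant with the donors the cells came from.

Downstream modules follow the field's standard recipes: Wilcoxon
rank-sum differential expression with a ratio fold change (significant
when |FC| > 1.25 and BH-FDR < 0.05), preranked GSEA on the fold-change
ranking (enriched when P < 0.05 and FDR < 0.25), single-sample gene-set
(ssGSEA) scores, a top-50-fold-change gene signature scored on bulk
samples and split at the median for Kaplan–Meier / log-rank and
stage-adjusted Cox regression, and per-cell-type composition tests.

A negative-binomial simulator (`synth_config()` /
`generate_paired_dataset()`) generates paired bulk + single-cell cohorts
with planted phenotype-associated subpopulations, planted expression
programs, survival structure, and full ground truth, so every stage of
the pipeline is testable without any external download.

## Worked example

```r
library(phenocell)

cfg <- synth_config(n_genes = 400, n_cells = 600, n_bulk = 60,
                    n_donors = 12, seed = 7)
d <- generate_paired_dataset(cfg)

sc_norm   <- normalize_cells(d$sc)
bulk_norm <- normalize_cells(d$bulk)
genes  <- intersect_genes(bulk_norm, sc_norm,
                          restrict_to = select_hvgs(sc_norm, 300))
design <- correlation_design(bulk_norm, sc_norm, genes)
graph  <- build_cell_graph(sc_norm, k = 10)

res <- alpha_search(design, d$phenotype$phenotype, graph, folds = 5)
res
#> <scissor_result> alpha = 0.20, lambda = 0.1126, 83 positive / 28 negative cells (18.5% selected)
```

The α-search stopped at the first α whose selection was below the 20%
cutoff; 83 cells associate with phenotype 1 and 28 with phenotype 0.
Against the simulator's ground truth, and against the donors the cells
came from:

```r
truth_evaluation(res, d$truth)
#>   direction n_selected n_truth precision    recall balanced_accuracy empty
#> 1       pos         83     116 0.5301205 0.3793103         0.6493659 FALSE
#> 2       neg         28     115 0.8214286 0.2000000         0.5948454 FALSE

rel <- reliability_test(res, d$cell_meta)
#> chi-square p = 0.0047, concordant direction: TRUE
```

Characterize the two sets and build the prognostic signature:

```r
de  <- wilcoxon_de(sc_norm, res$selected_pos, res$selected_neg)
sum(de$significant)
#> [1] 109
sig <- build_signature(de, n = 50)
sf  <- signature_survival(bulk_norm, sig, d$phenotype)
#> log-rank p = 0.00992; stage-adjusted HR = 2.96 (95% CI 1.35-6.48, p = 0.00653)
```

Bulk samples with a high signature score have about three times the
event hazard of low-score samples after adjusting for stage — the
simulator planted exactly this coupling between the positive
subpopulation's abundance and survival. Composition of the selected
sets:

```r
composition_test(res, setNames(d$cell_meta$cell_type, d$cell_meta$cell_id))
#>   cell_type count_pos count_neg   prop_pos  prop_neg            p          fdr star
#> 1       T01        44         0 0.53012048 0.0000000 7.087243e-07 1.771811e-06  ***
#> 2       T02         0        23 0.00000000 0.8214286 1.801204e-20 9.006019e-20  ***
#> 3       T03        35         0 0.42168675 0.0000000 3.286011e-05 5.476685e-05  ***
#> 4       T04         1         5 0.01204819 0.1785714 3.769021e-03 4.711276e-03   **
#> 5       T05         3         0 0.03614458 0.0000000 5.704348e-01 5.704348e-01   ns
```

The planted positive subtype (T01) dominates the positive set and the
planted negative subtype (T02) the negative set.

The whole flow — simulation through composition, with checksummed
intermediates — is wrapped in `run_pipeline(pipeline_config(...))`, with
a YAML-configurable shell entry point at `inst/scripts/run_pipeline.R`.

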
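Package: phenocell
Title: Phenotype-Guided Selection and Characterization of Single-Cell
    Subpopulations from Bulk Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates a bulk RNA-seq cohort carrying a binary phenotype
    with a single-cell RNA-seq atlas to identify phenotype-associated cell
    subpopulations.  A Pearson correlation matrix between bulk samples and
    single cells is used as the design of a network-regularized sparse
    regression (an L1 penalty combined with a quadratic cell-graph
    Laplacian penalty); cells with non-zero coefficients form
    phenotype-positive and phenotype-negative sets.  Downstream modules
    characterize the selected subpopulations: Wilcoxon rank-sum
    differential expression with fold-change and FDR filters, preranked
    gene-set enrichment analysis, single-sample gene-set (ssGSEA) scoring,
    top-fold-change gene signatures with Kaplan-Meier/log-rank and
    stage-adjusted Cox survival analysis, and cell-type composition tests.
    A negative-binomial paired-cohort simulator with planted associated
    subpopulations makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    survival,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    glmnet,
    fgsea,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
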
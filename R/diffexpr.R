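## Wilcoxon rank-sum differential expression between two cell groups and
## preranked gene-set enrichment on the resulting fold-change ranking.

# two-sided Wilcoxon rank-sum p; exact enumeration when both groups are
# small and tie-free, otherwise tie-corrected normal approximation
# (no continuity correction)
wilcox_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)   # no variation at all
  exact_ok <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = exact_ok, correct = FALSE)$p.value
  )
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two disjoint cell
#' groups on log-normalized expression, with a ratio-scale fold change
#' computed on de-logged means: `fc = (mean(expm1(x_A)) + pseudocount) /
#' (mean(expm1(x_B)) + pseudocount)`.  P values are BH-adjusted over the
#' tested genes and a gene is flagged significant when `fc > 1.25` or
#' `fc < 1/1.25` with `fdr < 0.05`.  Only genes detected (value > 0) in
#' at least `min_pct` of cells in one of the groups are tested.
#'
#' @param sc an [expression_matrix()] with `layer = "lognorm"`.
#' @param group_a,group_b disjoint cell-id vectors, each >= 3 cells.
#' @param pseudocount added to both de-logged means, default 1.
#' @param min_pct minimum detection fraction, default 0.10.
#' @param fc_threshold,fdr_threshold significance rule, defaults 1.25 and
#'   0.05.
#' @return a `de_table` data.frame: gene_id, fc, log2fc, pct_a, pct_b, p,
#'   fdr, significant; ordered by increasing p (ties by gene id).
#' @export
wilcoxon_de <- function(sc, group_a, group_b, pseudocount = 1,
                        min_pct = 0.10, fc_threshold = 1.25,
                        fdr_threshold = 0.05) {
  stopifnot(inherits(sc, "expr_matrix"))
  if (sc$layer != "lognorm") stop("wilcoxon_de expects a lognorm layer")
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 cells")
  }
  missing <- setdiff(c(group_a, group_b), sc$sample_ids)
  if (length(missing)) stop("unknown cells: ", paste(head(missing, 5), collapse = ", "))
  v <- dense_values(sc)
  va <- v[, group_a, drop = FALSE]
  vb <- v[, group_b, drop = FALSE]
  pct_a <- rowMeans(va > 0)
  pct_b <- rowMeans(vb > 0)
  keep <- pct_a >= min_pct | pct_b >= min_pct
  if (!any(keep)) stop("no gene passes the detection filter")
  genes <- sc$gene_ids[keep]
  mean_a <- rowMeans(expm1(va[keep, , drop = FALSE]))
  mean_b <- rowMeans(expm1(vb[keep, , drop = FALSE]))
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  p <- vapply(seq_along(genes), function(i) {
    wilcox_p(va[keep, , drop = FALSE][i, ], vb[keep, , drop = FALSE][i, ])
  }, 0)
  fdr <- p.adjust(p, method = "BH")
  significant <- de_significance(fc, fdr, fc_threshold, fdr_threshold)
  out <- data.frame(gene_id = genes, fc = fc, log2fc = log2(fc),
                    pct_a = pct_a[keep], pct_b = pct_b[keep],
                    p = p, fdr = fdr, significant = significant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Differential-expression significance rule
#'
#' A gene is significant when its ratio-scale fold change exceeds the
#' threshold in either direction (`fc > threshold` or
#' `fc < 1/threshold`) and its FDR is below the cutoff.  Defaults encode
#' the |FC| > 1.25 and FDR < 0.05 rule.
#'
#' @param fc ratio-scale fold change(s).
#' @param fdr BH-adjusted p value(s).
#' @param fc_threshold,fdr_threshold rule parameters.
#' @return logical vector.
#' @export
de_significance <- function(fc, fdr, fc_threshold = 1.25,
                            fdr_threshold = 0.05) {
  (fc > fc_threshold | fc < 1 / fc_threshold) & fdr < fdr_threshold
}

#' Gene-set enrichment significance rule
#'
#' A gene set is significantly enriched when `p < p_threshold` and
#' `fdr < fdr_threshold` (defaults 0.05 and 0.25).
#'
#' @param p permutation p value(s).
#' @param fdr BH-adjusted p value(s).
#' @param p_threshold,fdr_threshold rule parameters.
#' @return logical vector.
#' @export
gsea_significance <- function(p, fdr, p_threshold = 0.05,
                              fdr_threshold = 0.25) {
  p < p_threshold & fdr < fdr_threshold
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for a set of
# positions within a ranking of length n; wts are |score|^exponent
gsea_es <- function(inset, wts, return_path = FALSE) {
  n <- length(inset)
  k <- sum(inset)
  w_in <- wts * inset
  denom_in <- sum(w_in)
  w_in <- if (denom_in > 0) w_in / denom_in else inset / k
  step <- w_in - (!inset) / (n - k)
  path <- cumsum(step)
  es <- path[which.max(abs(path))]
  if (return_path) list(es = es, path = path) else es
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment of each gene set within a fixed
#' gene ranking (typically the DE fold changes).  The running sum gains
#' `|score|^weight_exponent` (normalized) at in-set genes and loses
#' `1/(N - |set|)` elsewhere; the enrichment score ES is the extreme
#' deviation.  Significance comes from gene-label permutations (random
#' same-size sets), two-tailed by ES sign; `NES = ES / mean(|permuted
#' ES|)` over permutations of matching sign, and FDR is BH across sets.
#' Ties in the ranking are broken by gene id so the walk is
#' deterministic.
#'
#' @param ranking named numeric vector, gene -> score (e.g. log2 fold
#'   change; the sign orients the two tails).
#' @param gene_sets list of [gene_set()] objects (or a named list of
#'   character vectors).
#' @param nperm number of permutations, default 1000.
#' @param weight_exponent KS weight exponent, default 1.
#' @param min_size,max_size retained set-size bounds after filtering to
#'   ranked genes (defaults 5 and 500); sets outside the bounds are
#'   dropped with a warning.
#' @param seed permutation seed.
#' @return a `gsea_table` data.frame: set_name, size, es, nes, p, fdr,
#'   significant (`p < 0.05 & fdr < 0.25`), leading_edge
#'   (comma-separated).
#' @export
preranked_gsea <- function(ranking, gene_sets, nperm = 1000,
                           weight_exponent = 1, min_size = 5,
                           max_size = 500, seed = 1L) {
  if (length(ranking) == 0) stop("empty ranking")
  if (is.null(names(ranking))) stop("ranking must be named by gene")
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- ranking[ord]
  n <- length(genes)
  wts <- abs(scores)^weight_exponent

  sets <- lapply(gene_sets, function(s) {
    members <- if (inherits(s, "gene_set")) s$members else s
    intersect(members, genes)
  })
  if (is.null(names(sets))) {
    names(sets) <- vapply(gene_sets, function(s)
      if (inherits(s, "gene_set")) s$name else "", "")
  }
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " gene set(s) outside size bounds [",
            min_size, ", ", max_size, "]: ",
            paste(head(names(sets)[!keep], 5), collapse = ", "))
  }
  if (!any(keep)) stop("no gene set within size bounds after filtering")
  sets <- sets[keep]

  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    k <- length(members)
    inset <- genes %in% members
    res <- gsea_es(inset, wts, return_path = TRUE)
    es <- res$es
    perm_es <- vapply(seq_len(nperm), function(b) {
      ins <- logical(n)
      ins[sample.int(n, k)] <- TRUE
      gsea_es(ins, wts)
    }, 0)
    same <- perm_es * sign(es) >= 0
    n_same <- sum(same)
    p <- if (n_same == 0) 1 / (nperm + 1) else
      (1 + sum(abs(perm_es[same]) >= abs(es))) / (1 + n_same)
    nes <- if (n_same == 0) NA_real_ else es / mean(abs(perm_es[same]))
    peak <- which.max(abs(res$path))
    le <- if (es >= 0) genes[seq_len(peak)][inset[seq_len(peak)]]
          else genes[peak:n][inset[peak:n]]
    data.frame(set_name = nm, size = k, es = es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- gsea_significance(out$p, out$fdr)
  out <- out[, c("set_name", "size", "es", "nes", "p", "fdr",
                 "significant", "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("gsea_table", "data.frame")
  out
}
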
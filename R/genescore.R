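## Single-sample gene-set (ssGSEA) scoring and rank-based score
## comparisons between cell groups.

#' Single-sample gene-set enrichment score
#'
#' For each column, genes are ranked by expression in decreasing order
#' (ties get average ranks) and the score is the sum over positions of
#' the difference between the weighted in-set cumulative fraction
#' (weights `rank^tau`, with rank counted so the top gene has the largest
#' value) and the uniform out-of-set cumulative fraction.  Rank-based, so
#' invariant to any strictly increasing transform of a column.  When
#' `normalize = TRUE` the scores are min-max rescaled across columns.
#'
#' @param expr an [expression_matrix()] (any layer; only ranks are used).
#' @param set a [gene_set()]; members absent from the matrix are dropped
#'   with a warning, and at least one must be present.
#' @param tau weighting exponent, default 0.25.
#' @param normalize min-max rescale across columns, default FALSE.
#' @return a `score_vector`: named numeric vector with attributes
#'   `set_name`, `tau`, `normalized`.
#' @export
ssgsea_score <- function(expr, set, tau = 0.25, normalize = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(set, "gene_set"))
  if (length(expr$gene_ids) < 2) stop("need at least 2 genes")
  members <- intersect(set$members, expr$gene_ids)
  if (length(members) == 0) {
    stop("no member of gene set '", set$name, "' is present in the matrix")
  }
  if (length(members) < length(set$members)) {
    warning("dropping ", length(set$members) - length(members),
            " absent gene(s) from set '", set$name, "'")
  }
  v <- dense_values(expr)
  n <- nrow(v)
  inset_by_gene <- expr$gene_ids %in% members
  n_out <- n - length(members)
  scores <- apply(v, 2, function(col) {
    # walk order: expression descending, gene id ascending on ties
    ord <- order(-col, expr$gene_ids)
    inset <- inset_by_gene[ord]
    # rank statistic: the top-expressed gene carries the largest weight n
    r <- rank(col, ties.method = "average")[ord]
    w <- r^tau * inset
    denom <- sum(w)
    p_in <- if (denom > 0) cumsum(w) / denom else cumsum(inset) / sum(inset)
    p_out <- if (n_out > 0) cumsum(!inset) / n_out else rep(0, n)
    if (n_out == 0) 0 else sum(p_in - p_out)
  })
  names(scores) <- expr$sample_ids
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  structure(scores, set_name = set$name, tau = tau, normalized = normalize,
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> set '%s', %d columns, tau = %.2f%s\n",
              attr(x, "set_name"), length(x), attr(x, "tau"),
              if (attr(x, "normalized")) ", min-max normalized" else ""))
  print(unclass(head(x)))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(id = names(x), score = as.numeric(x),
             set_name = attr(x, "set_name"), stringsAsFactors = FALSE)
}

#' Compare gene-set scores between two groups
#'
#' Reports group medians and the two-sided Wilcoxon rank-sum p value
#' (exact for small tie-free groups, tie-corrected normal approximation
#' otherwise).
#'
#' @param scores a [ssgsea_score()] result (or named numeric vector).
#' @param group_labels named vector (or vector aligned with `scores`)
#'   with exactly two distinct labels.
#' @return list with `medians` (named), `p`, `n` (group sizes).
#' @export
compare_scores <- function(scores, group_labels) {
  if (!is.null(names(group_labels))) {
    if (!all(names(scores) %in% names(group_labels))) {
      stop("unknown labels: scores not covered by group_labels")
    }
    group_labels <- group_labels[names(scores)]
  }
  if (length(group_labels) != length(scores)) {
    stop("group_labels length does not match scores")
  }
  groups <- unique(as.character(group_labels))
  if (length(groups) != 2) stop("exactly two groups are required")
  a <- as.numeric(scores[group_labels == groups[1]])
  b <- as.numeric(scores[group_labels == groups[2]])
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  list(medians = setNames(c(median(a), median(b)), groups),
       p = wilcox_p(a, b),
       n = setNames(c(length(a), length(b)), groups))
}
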
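#' Bulk-by-cell correlation design
#'
#' Computes the Pearson correlation of every bulk sample with every single
#' cell over a common gene list; this matrix is the regression design that
#' links the bulk phenotype to individual cells.  Columns (cells) are then
#' standardized to mean 0 and unit variance across bulk samples so that
#' the sparsity penalty acts uniformly; the raw correlations are kept in
#' `$raw`.
#'
#' @param bulk,sc [expression_matrix()] objects covering `genes`
#'   (normalized layers recommended).
#' @param genes common gene list (>= 3 genes).
#' @return a `correlation_design`: list with `S` (standardized n x m
#'   matrix), `raw` (Pearson correlations), `gene_universe`.
#' @export
correlation_design <- function(bulk, sc, genes) {
  if (length(genes) < 3) stop("need at least 3 genes")
  miss_b <- setdiff(genes, bulk$gene_ids)
  miss_s <- setdiff(genes, sc$gene_ids)
  if (length(miss_b) || length(miss_s)) {
    stop("genes missing from input matrices: ",
         paste(head(c(miss_b, miss_s), 5), collapse = ", "))
  }
  bm <- dense_values(bulk)[genes, , drop = FALSE]
  sm <- dense_values(sc)[genes, , drop = FALSE]
  sd_b <- apply(bm, 2, sd)
  sd_s <- apply(sm, 2, sd)
  if (any(sd_b == 0)) {
    stop("zero-variance gene vector for bulk sample(s): ",
         paste(head(colnames(bm)[sd_b == 0], 5), collapse = ", "))
  }
  if (any(sd_s == 0)) {
    stop("zero-variance gene vector for cell(s): ",
         paste(head(colnames(sm)[sd_s == 0], 5), collapse = ", "))
  }
  raw <- cor(bm, sm)
  S <- scale(raw)
  # cells whose correlation profile is constant across bulk samples carry
  # no phenotype information; their standardized column is set to zero
  const <- attr(S, "scaled:scale") == 0 | !is.finite(attr(S, "scaled:scale"))
  if (any(const)) S[, const] <- 0
  S <- S[, , drop = FALSE]
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  structure(list(S = S, raw = raw, gene_universe = genes),
            class = "correlation_design")
}

#' @export
print.correlation_design <- function(x, ...) {
  cat(sprintf("<correlation_design> %d bulk samples x %d cells over %d genes\n",
              nrow(x$S), ncol(x$S), length(x$gene_universe)))
  invisible(x)
}

#' Cell-cell similarity graph and its normalized Laplacian
#'
#' Builds a k-nearest-neighbour graph on cells in a reduced space (the top
#' principal directions of the log-normalized expression matrix, or of the
#' correlation design when one is supplied), symmetrized by union with
#' binary weights.  The normalized Laplacian `L = I - D^{-1/2} A D^{-1/2}`
#' is the quadratic penalty of the network-regularized regression;
#' isolated vertices get zero Laplacian rows so their penalty reduces to
#' the pure L1 term.
#'
#' @param x an [expression_matrix()] with `layer = "lognorm"`, or a
#'   `correlation_design` (cells embedded via their correlation profiles).
#' @param k neighbours per cell (`m > k > 0`).
#' @param npcs number of principal directions for the embedding.
#' @return a `cell_graph`: list with `adjacency` (sparse symmetric binary,
#'   zero diagonal), `laplacian` (sparse, PSD), `k`, `npcs`, `cell_ids`.
#' @export
build_cell_graph <- function(x, k = 10, npcs = 30) {
  if (k <= 0) stop("k must be positive")
  if (inherits(x, "correlation_design")) {
    feats <- t(x$S)                       # cells x bulk-profile features
  } else if (inherits(x, "expr_matrix")) {
    if (x$layer != "lognorm") stop("build_cell_graph expects a lognorm layer")
    feats <- t(dense_values(x))           # cells x genes
  } else stop("x must be an expr_matrix or correlation_design")
  m <- nrow(feats)
  if (m <= k) stop("need more cells than neighbours (m > k)")
  npcs <- min(npcs, m - 1, ncol(feats))
  emb <- if (ncol(feats) > npcs) {
    prcomp(feats, rank. = npcs, center = TRUE, scale. = FALSE)$x
  } else scale(feats, center = TRUE, scale = FALSE)

  # exact kNN from the pairwise distance matrix; ties broken by index
  d2 <- as.matrix(dist(emb))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  ii <- rep(seq_len(m), k)
  jj <- as.vector(nn)
  A <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, m))
  A <- as(pmin(A + Matrix::t(A), 1), "CsparseMatrix")   # union symmetrization
  diag(A) <- 0
  A <- Matrix::drop0(A)

  deg <- Matrix::colSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dm <- Diagonal(m, inv_sqrt)
  L <- Diagonal(m, as.numeric(deg > 0)) - Dm %*% A %*% Dm
  L <- as(Matrix::forceSymmetric((L + Matrix::t(L)) / 2), "CsparseMatrix")
  cell_ids <- rownames(feats)
  structure(list(adjacency = A, laplacian = L, k = k, npcs = npcs,
                 cell_ids = cell_ids),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, k = %d, %d undirected edges\n",
              nrow(x$adjacency), x$k, sum(x$adjacency) / 2))
  invisible(x)
}
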
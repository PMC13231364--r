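#' Expression matrix container
#'
#' A light container for a gene x sample (bulk) or gene x cell
#' (single-cell) expression matrix.  Rows are genes, columns are samples or
#' cells.  The `layer` records whether values are raw counts or
#' log-normalized expression.
#'
#' @param values numeric matrix (base or `Matrix` sparse), genes in rows.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample/cell identifiers;
#'   defaults to `colnames(values)`.
#' @param layer `"counts"` (non-negative) or `"lognorm"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids`, `layer`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames on values)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("dimensions of values do not match identifier lists: ",
         nrow(values), "x", ncol(values), " vs ",
         length(gene_ids), " genes / ", length(sample_ids), " samples")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (layer == "counts" && min_value(values) < 0) {
    stop("counts layer must be non-negative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, layer = layer),
            class = "expr_matrix")
}

min_value <- function(x) {
  if (is(x, "sparseMatrix")) min(x@x, 0) else min(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, layer = %s%s\n",
              length(x$gene_ids), length(x$sample_ids), x$layer,
              if (is(x$values, "sparseMatrix")) " (sparse)" else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# dense numeric matrix view (sparse inputs are densified)
dense_values <- function(x) {
  v <- x$values
  if (is(v, "sparseMatrix")) as.matrix(v) else v
}

#' Read an expression matrix from disk
#'
#' Two formats are supported: a dense TSV with gene identifiers in the
#' first column and sample identifiers in the header row, and the
#' MatrixMarket sparse-coordinate layout used for single-cell counts,
#' where `path` is a directory containing `matrix.mtx` plus `features.tsv`
#' (gene ids, one per line) and `barcodes.tsv` (cell ids, one per line).
#'
#' @param path file (tsv) or directory (mtx).
#' @param format `"tsv"` or `"mtx"`.
#' @param layer layer flag recorded on the result, default `"counts"`.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        layer = c("counts", "lognorm")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                     check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    expression_matrix(m, layer = layer)
  } else {
    mtx_file <- file.path(path, "matrix.mtx")
    feat_file <- file.path(path, "features.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, feat_file, bc_file)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- as(readMM(mtx_file), "CsparseMatrix")
    genes <- read.delim(feat_file, header = FALSE)[[1]]
    cells <- read.delim(bc_file, header = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("MTX dimensions (", nrow(m), "x", ncol(m),
           ") do not match features/barcodes files (",
           length(genes), "/", length(cells), ")")
    }
    expression_matrix(m, gene_ids = genes, sample_ids = cells, layer = layer)
  }
}

#' Write an expression matrix to disk
#'
#' @param x an [expression_matrix()].
#' @param path output file (tsv) or directory (mtx).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = x$gene_ids, as.matrix(x$values),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeMM(as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"),
            file.path(path, "matrix.mtx"))
    writeLines(x$gene_ids, file.path(path, "features.tsv"))
    writeLines(x$sample_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Log-normalize cells or samples
#'
#' Column-wise library-size normalization followed by a log transform:
#' each entry becomes `ln(1 + scale * count / column_total)`.  This is the
#' standard per-cell normalization used ahead of correlation-based
#' integration; note the natural logarithm.
#'
#' @param x an [expression_matrix()] with `layer = "counts"`.
#' @param scale scale factor, default `1e4`.
#' @return an [expression_matrix()] with `layer = "lognorm"`.
#' @export
normalize_cells <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "counts") stop("normalize_cells expects a counts layer")
  totals <- Matrix::colSums(x$values)
  if (any(totals == 0)) {
    stop("zero library size in column(s): ",
         paste(x$sample_ids[totals == 0], collapse = ", "))
  }
  v <- dense_values(x)
  v <- log1p(sweep(v, 2, totals / scale, "/"))
  expression_matrix(v, x$gene_ids, x$sample_ids, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the variance of the log-normalized
#' values divided by the value predicted from a degree-2 polynomial fit of
#' log-variance on log-mean across genes (a smoother-free mean-variance
#' trend).  Genes with zero variance are never selected.
#'
#' @param x an [expression_matrix()] with `layer = "lognorm"`.
#' @param n number of genes to return.
#' @return character vector of `n` gene identifiers, ordered by decreasing
#'   standardized variance (ties broken by gene id).
#' @export
select_hvgs <- function(x, n = 2000) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "lognorm") stop("select_hvgs expects a lognorm layer")
  if (n > length(x$gene_ids)) {
    stop("n (", n, ") exceeds the number of genes (", length(x$gene_ids), ")")
  }
  v <- dense_values(x)
  mu <- rowMeans(v)
  va <- apply(v, 1, var)
  ok <- va > 0 & mu > 0
  if (!any(ok)) stop("all genes have zero variance")
  lm_trend <- lm(log(va[ok]) ~ poly(log(mu[ok]), degree = 2, raw = TRUE))
  std_var <- rep(0, length(va))
  std_var[ok] <- va[ok] / exp(unname(fitted(lm_trend)))
  ord <- order(-std_var, x$gene_ids)
  x$gene_ids[ord][seq_len(n)]
}

#' Common genes between bulk and single-cell matrices
#'
#' @param bulk,sc [expression_matrix()] objects.
#' @param restrict_to optional gene list (e.g. common highly variable
#'   genes) the intersection is further restricted to.
#' @param drop_ribosomal drop identifiers with an RPL/RPS prefix
#'   (case-insensitive); off by default.
#' @return sorted character vector of shared gene identifiers.
#' @export
intersect_genes <- function(bulk, sc, restrict_to = NULL,
                            drop_ribosomal = FALSE) {
  genes <- intersect(bulk$gene_ids, sc$gene_ids)
  if (!is.null(restrict_to)) genes <- intersect(genes, restrict_to)
  if (drop_ribosomal) genes <- genes[!grepl("^RP[LS]", genes, ignore.case = TRUE)]
  if (length(genes) == 0) stop("empty gene intersection")
  sort(genes)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of `gene_set` objects (see [gene_set()]).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1], unique(f[-(1:2)]), note = f[2])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$note)) s$note else "na", s$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene set
#'
#' @param name set name.
#' @param members character vector of member genes (non-empty, unique).
#' @param note free-text provenance note.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members, note = "") {
  members <- as.character(members)
  if (length(members) == 0) stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) members <- unique(members)
  structure(list(name = name, members = members, note = note),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Validate a phenotype table
#'
#' Checks the bulk sample metadata contract: unique `sample_id`,
#' `phenotype` in {0,1} (or numeric dosage), non-negative `time`, `event`
#' in {0,1}.
#'
#' @param pheno data.frame with columns `sample_id`, `phenotype`, and
#'   optionally `stage`, `time`, `event`, `batch`.
#' @return the validated data.frame, invisibly.
#' @export
validate_phenotype <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  req <- c("sample_id", "phenotype")
  if (!all(req %in% names(pheno))) {
    stop("phenotype table must contain columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(pheno$sample_id)) stop("duplicate sample_id in phenotype table")
  if ("time" %in% names(pheno) && any(pheno$time < 0, na.rm = TRUE)) {
    stop("negative survival times")
  }
  if ("event" %in% names(pheno) && !all(pheno$event %in% c(0, 1))) {
    stop("event indicator must be 0/1")
  }
  invisible(pheno)
}
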
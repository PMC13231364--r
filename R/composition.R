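## Cell-type composition comparisons between the selected cell sets, and
## per-donor proportion regression with a dataset covariate.

star_label <- function(fdr) {
  ifelse(fdr < 0.001, "***", ifelse(fdr < 0.01, "**",
         ifelse(fdr < 0.05, "*", "ns")))
}

#' Compare cell-type composition between selected sets
#'
#' For every cell type, a 2x2 table (in-type vs not, positive vs negative
#' set) is tested by chi-square without continuity correction, switching
#' to Fisher's exact test when any expected count is below 5; p values
#' are BH-adjusted across cell types.  Proportions are within each
#' selected set (denominators are the set sizes).
#'
#' @param result a `scissor_result` (or list with `selected_pos`,
#'   `selected_neg`).
#' @param cell_types named character vector, cell id -> cell type.
#' @return a `composition_table` data.frame: cell_type, count_pos,
#'   count_neg, prop_pos, prop_neg, p, fdr, star.
#' @export
composition_test <- function(result, cell_types) {
  pos <- result$selected_pos; neg <- result$selected_neg
  if (length(pos) == 0 || length(neg) == 0) stop("empty selected set(s)")
  sel <- c(pos, neg)
  if (!all(sel %in% names(cell_types))) stop("selected cell without a cell type")
  types <- sort(unique(cell_types[sel]))
  tp <- table(factor(cell_types[pos], levels = types))
  tn <- table(factor(cell_types[neg], levels = types))
  rows <- lapply(types, function(tt) {
    tab <- matrix(c(tp[[tt]], tn[[tt]],
                    length(pos) - tp[[tt]], length(neg) - tn[[tt]]),
                  2, 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p <- if (any(expected < 5)) {
      fisher.test(tab)$p.value
    } else {
      chisq.test(tab, correct = FALSE)$p.value
    }
    data.frame(cell_type = tt, count_pos = tp[[tt]], count_neg = tn[[tt]],
               prop_pos = tp[[tt]] / length(pos),
               prop_neg = tn[[tt]] / length(neg),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$star <- star_label(out$fdr)
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Per-donor proportion regression with a dataset covariate
#'
#' For every cell type, ordinary least squares of the per-donor
#' proportion on the donor phenotype plus a dataset indicator; the
#' reported p is the two-sided t-test on the phenotype coefficient, BH
#' adjusted across cell types.  Collinear phenotype/dataset designs
#' (e.g. all phenotype-1 donors in one dataset) are flagged with no
#' estimate.
#'
#' @param proportions donors x cell-types numeric matrix or data.frame of
#'   per-donor cell-type proportions.
#' @param phenotype per-donor 0/1 phenotype.
#' @param dataset per-donor dataset label; a single dataset reduces the
#'   model to a two-group comparison of proportions.
#' @return data.frame: cell_type, coefficient, p, fdr, flagged.
#' @export
donor_proportion_regression <- function(proportions, phenotype, dataset = NULL) {
  proportions <- as.matrix(proportions)
  n <- nrow(proportions)
  if (length(phenotype) != n) stop("phenotype length mismatch")
  if (min(table(phenotype)) < 3) stop("need >= 3 donors per phenotype group")
  if (is.null(dataset)) dataset <- rep("ds1", n)
  dataset <- as.factor(dataset)
  multi_ds <- nlevels(droplevels(dataset)) > 1
  collinear <- FALSE
  if (multi_ds) {
    X <- stats::model.matrix(~ phenotype + dataset)
    collinear <- qr(X)$rank < ncol(X)
  }
  rows <- lapply(colnames(proportions), function(tt) {
    if (collinear) {
      return(data.frame(cell_type = tt, coefficient = NA_real_,
                        p = NA_real_, flagged = TRUE))
    }
    if (var(proportions[, tt]) == 0) {
      # constant response: no association by definition
      return(data.frame(cell_type = tt, coefficient = 0, p = 1,
                        flagged = FALSE))
    }
    df <- data.frame(prop = proportions[, tt], phenotype = phenotype,
                     dataset = dataset)
    fit <- if (multi_ds) lm(prop ~ phenotype + dataset, df)
           else lm(prop ~ phenotype, df)
    sm <- summary(fit)$coefficients
    if (!"phenotype" %in% rownames(sm) || anyNA(coef(fit))) {
      return(data.frame(cell_type = tt, coefficient = NA_real_,
                        p = NA_real_, flagged = TRUE))
    }
    data.frame(cell_type = tt, coefficient = sm["phenotype", "Estimate"],
               p = sm["phenotype", "Pr(>|t|)"], flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-donor cell-type proportion matrix
#'
#' @param cell_meta data.frame with `donor` and `cell_type` columns.
#' @return donors x cell-types matrix of proportions (rows sum to 1).
#' @export
donor_proportions <- function(cell_meta) {
  tab <- table(cell_meta$donor, cell_meta$cell_type)
  prop <- as.matrix(prop.table(tab, 1))
  prop[order(rownames(prop)), , drop = FALSE]
}
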
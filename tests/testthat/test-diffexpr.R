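# small lognorm matrix with two 4-cell groups and controllable genes
make_de_matrix <- function() {
  set.seed(21)
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  m <- rbind(
    up   = c(3.1, 3.3, 3.0, 3.2,  1.0, 1.2, 0.9, 1.1),
    down = c(0.8, 1.1, 1.0, 0.9,  2.9, 3.1, 3.0, 3.2),
    flat = rep(2, 8),
    noise = rnorm(8, 1, 0.05))
  colnames(m) <- c(a, b)
  list(em = expression_matrix(m, layer = "lognorm"), a = a, b = b)
}

test_that("wilcoxon_de matches exact enumeration and the FC definition", {
  x <- make_de_matrix()
  de <- wilcoxon_de(x$em, x$a, x$b, min_pct = 0)
  de_up <- de[de$gene_id == "up", ]
  # exact p for fully separated 4 vs 4 = 2/70
  expect_equal(de_up$p, 2 / 70)
  expect_equal(de_up$p, oracle_wilcox_exact(c(3.1, 3.3, 3.0, 3.2),
                                            c(1.0, 1.2, 0.9, 1.1)))
  # fc from de-logged means with pseudocount 1
  fc_expected <- (mean(expm1(c(3.1, 3.3, 3.0, 3.2))) + 1) /
    (mean(expm1(c(1.0, 1.2, 0.9, 1.1))) + 1)
  expect_equal(de_up$fc, fc_expected)
  # identical gene: fc = 1, p = 1
  de_flat <- de[de$gene_id == "flat", ]
  expect_equal(de_flat$fc, 1)
  expect_equal(de_flat$p, 1)
})

test_that("3-vs-3 separated toy gives exact p = 0.1", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("g", paste0("c", 1:6)))
  em <- expression_matrix(rbind(m, pad = c(1, 1, 2, 1, 1, 2)),
                          layer = "lognorm")
  de <- wilcoxon_de(em, paste0("c", 1:3), paste0("c", 4:6), min_pct = 0)
  expect_equal(de[de$gene_id == "g", "p"], 0.1)
  expect_equal(oracle_wilcox_exact(1:3, 4:6), 0.1)
})

test_that("group swap inverts fold changes and keeps p values", {
  x <- make_de_matrix()
  de_ab <- wilcoxon_de(x$em, x$a, x$b, min_pct = 0)
  de_ba <- wilcoxon_de(x$em, x$b, x$a, min_pct = 0)
  merged <- merge(de_ab, de_ba, by = "gene_id")
  expect_equal(merged$fc.x, 1 / merged$fc.y)
  expect_equal(merged$p.x, merged$p.y)
})

test_that("p values are invariant under monotone transforms", {
  x <- make_de_matrix()
  de1 <- wilcoxon_de(x$em, x$a, x$b, min_pct = 0)
  em2 <- expression_matrix(exp(x$em$values) - 0.5, layer = "lognorm")
  de2 <- wilcoxon_de(em2, x$a, x$b, min_pct = 0)
  merged <- merge(de1, de2, by = "gene_id")
  expect_equal(merged$p.x, merged$p.y)
})

test_that("significance flag applies the FC > 1.25 & FDR < 0.05 rule", {
  expect_identical(
    de_significance(fc = c(1.30, 1.20, 0.70, 1.30),
                    fdr = c(0.01, 0.001, 0.01, 0.4)),
    c(TRUE, FALSE, TRUE, FALSE))
})

test_that("input contract violations are rejected", {
  x <- make_de_matrix()
  expect_error(wilcoxon_de(x$em, x$a, c(x$b, x$a[1])), "overlap")
  expect_error(wilcoxon_de(x$em, x$a[1:2], x$b), "at least 3")
  counts <- expression_matrix(matrix(1:8, 4, 2,
    dimnames = list(paste0("g", 1:4), c("c1", "c2"))), layer = "counts")
  expect_error(wilcoxon_de(counts, "c1", "c2"), "lognorm")
})

test_that("BH rejections are monotone in the FDR level", {
  d <- small_dataset()
  norm <- normalize_cells(d$sc)
  assoc <- d$truth$cell_assoc
  de <- wilcoxon_de(norm, names(assoc)[assoc == 1][1:40],
                    names(assoc)[assoc == 0][1:40])
  rej10 <- de$gene_id[de$fdr < 0.10]
  rej05 <- de$gene_id[de$fdr < 0.05]
  rej01 <- de$gene_id[de$fdr < 0.01]
  expect_true(all(rej01 %in% rej05))
  expect_true(all(rej05 %in% rej10))
  # planted program genes dominate the significant up-regulated genes
  up <- de$gene_id[de$significant & de$fc > 1]
  expect_gt(mean(up %in% d$truth$program_genes_pos), 0.5)
})

# --- preranked GSEA --------------------------------------------------------

toy_ranking <- function() {
  setNames(seq(2, -2, length.out = 10), paste0("g", 1:10))
}

test_that("ES matches the hand-computed running sum on a 10-gene toy", {
  ranking <- toy_ranking()
  members <- c("g1", "g2", "g3")     # ranks 1-3
  res <- preranked_gsea(ranking, list(top = gene_set("top", members)),
                        nperm = 200, min_size = 3, seed = 1)
  es_oracle <- oracle_gsea_es(names(ranking), as.numeric(ranking), members)
  expect_equal(res$es, es_oracle)
  expect_gt(res$es, 0)
  expect_identical(res$leading_edge, "g1,g2,g3")
})

test_that("single top gene with min_size override walks to ES = 1", {
  ranking <- toy_ranking()
  res <- preranked_gsea(ranking, list(one = gene_set("one", "g1")),
                        nperm = 100, min_size = 1, seed = 1)
  expect_equal(res$es, 1)
})

test_that("set spanning all ranked genes is excluded by the size rule", {
  ranking <- toy_ranking()
  expect_error(
    suppressWarnings(
      preranked_gsea(ranking, list(all = gene_set("all", names(ranking))),
                     nperm = 50, min_size = 1, max_size = 500, seed = 1)),
    "no gene set within size bounds")
})

test_that("ES ignores identities of out-of-set genes and perms are seeded", {
  ranking <- toy_ranking()
  members <- c("g2", "g5", "g6")
  r1 <- preranked_gsea(ranking, list(s = gene_set("s", members)),
                       nperm = 300, min_size = 3, seed = 7)
  # relabel out-of-set genes (scores unchanged)
  ranking2 <- ranking
  names(ranking2)[!names(ranking2) %in% members] <-
    paste0("x", seq_len(7))
  r2 <- preranked_gsea(ranking2, list(s = gene_set("s", members)),
                       nperm = 300, min_size = 3, seed = 7)
  expect_equal(r1$es, r2$es)
  expect_equal(r1$p, r2$p)
  r3 <- preranked_gsea(ranking, list(s = gene_set("s", members)),
                       nperm = 300, min_size = 3, seed = 7)
  expect_identical(r1$p, r3$p)
})

test_that("ES agrees with fgsea's statistic on random rankings", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:5) {
    ranking <- setNames(rnorm(40), paste0("g", 1:40))
    ranking <- sort(ranking, decreasing = TRUE)
    members <- sample(names(ranking), 8)
    mine <- preranked_gsea(ranking, list(s = gene_set("s", members)),
                           nperm = 10, seed = 1)$es
    ref <- fgsea::calcGseaStat(
      sort(ranking, decreasing = TRUE),
      selectedStats = which(names(sort(ranking, decreasing = TRUE))
                            %in% members),
      gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("enrichment flag applies the P < 0.05 & FDR < 0.25 rule", {
  expect_true(gsea_significance(0.04, 0.20))
  expect_false(gsea_significance(0.04, 0.30))
  expect_false(gsea_significance(0.06, 0.20))
})
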
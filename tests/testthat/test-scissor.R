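# --- correlation design ----------------------------------------------------

test_that("correlation design matches direct Pearson computation", {
  # 3-gene toy: r((1,2,3), (2,4,7)) by the closed-form Pearson formula
  bulk <- expression_matrix(matrix(c(1, 2, 3), 3, 1,
            dimnames = list(paste0("g", 1:3), "s1")), layer = "lognorm")
  sc <- expression_matrix(matrix(c(2, 4, 7, 3, 2, 1, 1, 2, 3), 3, 3,
            dimnames = list(paste0("g", 1:3), c("c1", "c2", "c3"))),
            layer = "lognorm")
  des <- correlation_design(bulk, sc, paste0("g", 1:3))
  # closed form: cov / (sd_x * sd_y) = 2.5 / (1 * sqrt(114/18))
  expect_equal(des$raw["s1", "c1"], 2.5 / sqrt(114 / 18), tolerance = 1e-12)
  expect_equal(des$raw["s1", "c1"], 0.9933993, tolerance = 1e-6)
  # identical profile -> raw correlation exactly 1
  expect_equal(des$raw["s1", "c3"], 1)
  # affine negative transform -> raw correlation -1
  expect_equal(des$raw["s1", "c2"], -1)
})

test_that("design columns are standardized and degenerate inputs rejected", {
  d <- small_dataset()
  norm_sc <- normalize_cells(d$sc)
  norm_bulk <- normalize_cells(d$bulk)
  genes <- intersect_genes(norm_bulk, norm_sc)
  des <- correlation_design(norm_bulk, norm_sc, genes[1:100])
  expect_equal(unname(colMeans(des$S)), rep(0, ncol(des$S)), tolerance = 1e-12)
  nonzero <- apply(des$S, 2, sd) > 0
  expect_equal(unname(apply(des$S[, nonzero], 2, sd)),
               rep(1, sum(nonzero)), tolerance = 1e-12)
  expect_true(all(des$raw >= -1 & des$raw <= 1))

  flat <- norm_bulk
  flat$values[genes[1:100], 1] <- 5
  expect_error(correlation_design(flat, norm_sc, genes[1:100]),
               "zero-variance")
  expect_error(correlation_design(norm_bulk, norm_sc, genes[1:2]),
               "at least 3")
})

# --- cell graph ------------------------------------------------------------

test_that("cell graph matches brute-force kNN enumeration on a 5-cell toy", {
  # cells on a line: 0, 1, 2, 10, 11 (one feature, k = 1)
  m <- matrix(c(0, 1, 2, 10, 11), 1, 5,
              dimnames = list("g1", paste0("c", 1:5)))
  em <- expression_matrix(rbind(m, g2 = 0), layer = "lognorm")
  g <- build_cell_graph(em, k = 1, npcs = 2)
  # directed 1-NN: c1->c2, c2->c1 (tie c1/c3 broken by index), c3->c2,
  # c4->c5, c5->c4; union edges: {1,2}, {2,3}, {4,5}
  expected <- Matrix::sparseMatrix(i = c(1, 2, 2, 3, 4, 5),
                                   j = c(2, 1, 3, 2, 5, 4),
                                   x = 1, dims = c(5, 5))
  expect_equal(as.matrix(g$adjacency), as.matrix(expected),
               ignore_attr = TRUE)
})

test_that("graph Laplacian is PSD with constant nullspace per component", {
  d <- small_dataset()
  norm <- normalize_cells(d$sc)
  sub <- expression_matrix(norm$values[, 1:150], layer = "lognorm")
  g <- build_cell_graph(sub, k = 5, npcs = 10)
  A <- as.matrix(g$adjacency)
  expect_true(isSymmetric(A))
  expect_equal(unname(diag(A)), rep(0, nrow(A)))
  L <- as.matrix(g$laplacian)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  # x = D^{1/2} * 1 lies in the nullspace of the normalized Laplacian
  x <- sqrt(Matrix::colSums(g$adjacency))
  expect_lt(abs(sum(x * (L %*% x))), 1e-10)
  # identical cells are always joined
  dup <- expression_matrix(cbind(norm$values[, 1:80],
                                 dup1 = norm$values[, 1],
                                 dup2 = norm$values[, 1]),
                           layer = "lognorm")
  g2 <- build_cell_graph(dup, k = 3, npcs = 10)
  expect_equal(as.numeric(g2$adjacency[81, 82]), 1)
  expect_error(build_cell_graph(sub, k = 0), "positive")
  expect_error(build_cell_graph(sub, k = 150), "m > k")
})

# --- solver ----------------------------------------------------------------

toy_gaussian <- function(seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(24), 6, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  X <- scale(X)
  y <- drop(X %*% c(1.5, 0, -1, 0)) + rnorm(6, sd = 0.2)
  list(X = X, y = y)
}

test_that("alpha = 1 fit matches the coordinate-descent lasso oracle", {
  toy <- toy_gaussian()
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- fit_network_lasso(toy$X, toy$y, graph = NULL, alpha = 1,
                             lam = lam, family = "gaussian", tol = 1e-14,
                             maxit = 100000)
    oracle <- oracle_cd_enet(toy$X, toy$y, lam, a = 1)
    expect_equal(as.numeric(fit), oracle$beta, tolerance = 1e-6)
    expect_equal(attr(fit, "intercept"), oracle$b0, tolerance = 1e-6)
    expect_lt(kkt_residual(toy$X, toy$y, NULL, 1, lam, fit, "gaussian"),
              1e-6)
  }
})

test_that("self-loop-only graph reproduces the elastic net", {
  toy <- toy_gaussian(2)
  eye_graph <- list(laplacian = Matrix::Diagonal(4))
  for (alpha in c(0.3, 0.5, 0.8)) {
    lam <- 0.2
    fit <- fit_network_lasso(toy$X, toy$y, eye_graph, alpha = alpha,
                             lam = lam, family = "gaussian", tol = 1e-14,
                             maxit = 100000)
    oracle <- oracle_cd_enet(toy$X, toy$y, lam, a = alpha)
    expect_equal(as.numeric(fit), oracle$beta, tolerance = 1e-6)
  }
})

test_that("elastic-net fits agree with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  toy <- toy_gaussian(3)
  # glmnet scales the response to unit (population) variance internally;
  # pre-scaling y makes the two objectives identical at the same lambda
  y <- toy$y / sqrt(mean((toy$y - mean(toy$y))^2))
  eye_graph <- list(laplacian = Matrix::Diagonal(4))
  lam <- 0.15
  for (alpha in c(1, 0.5)) {
    fit <- fit_network_lasso(toy$X, y, eye_graph, alpha = alpha,
                             lam = lam, family = "gaussian", tol = 1e-14,
                             maxit = 100000)
    gfit <- glmnet::glmnet(toy$X, y, alpha = alpha, lambda = lam,
                           standardize = FALSE, thresh = 1e-14)
    expect_equal(as.numeric(fit), as.numeric(gfit$beta), tolerance = 1e-5)
  }
})

test_that("large lambda shrinks everything to zero and support shrinks with lambda", {
  toy <- toy_gaussian(1)
  fit <- fit_network_lasso(toy$X, toy$y, NULL, alpha = 1, lam = 100,
                           family = "gaussian")
  expect_true(all(fit == 0))
  # support size non-increasing along the path, matching the oracle
  grid <- c(1, 0.5, 0.25, 0.1, 0.05, 0.01)
  supports <- integer(0)
  for (lam in grid) {
    fit <- fit_network_lasso(toy$X, toy$y, NULL, alpha = 1, lam = lam,
                             family = "gaussian", tol = 1e-13, maxit = 100000)
    oracle <- oracle_cd_enet(toy$X, toy$y, lam, a = 1)
    expect_equal(which(as.numeric(fit) != 0), which(abs(oracle$beta) > 1e-9))
    supports <- c(supports, sum(fit != 0))
  }
  expect_true(all(diff(supports) >= 0))
})

test_that("binomial fits satisfy the KKT conditions", {
  set.seed(5)
  X <- scale(matrix(rnorm(80), 20, 4))
  y <- as.integer(drop(X %*% c(2, 0, -2, 0)) + rnorm(20) > 0)
  eye_graph <- list(laplacian = Matrix::Diagonal(4))
  for (alpha in c(1, 0.5)) {
    fit <- fit_network_lasso(X, y, eye_graph, alpha = alpha, lam = 0.05,
                             family = "binomial", tol = 1e-14, maxit = 100000)
    expect_lt(kkt_residual(X, y, eye_graph, alpha, 0.05, fit, "binomial"),
              1e-6)
  }
})

test_that("permuting cell order permutes coefficients identically", {
  set.seed(6)
  X <- scale(matrix(rnorm(60), 10, 6,
                    dimnames = list(NULL, paste0("c", 1:6))))
  y <- rnorm(10)
  L <- Matrix::Diagonal(6)
  fit <- fit_network_lasso(X, y, list(laplacian = L), alpha = 0.6,
                           lam = 0.1, family = "gaussian", tol = 1e-13,
                           maxit = 100000)
  perm <- c(3, 1, 6, 2, 5, 4)
  fit_p <- fit_network_lasso(X[, perm], y, list(laplacian = L),
                             alpha = 0.6, lam = 0.1, family = "gaussian",
                             tol = 1e-13, maxit = 100000)
  expect_equal(as.numeric(fit_p), as.numeric(fit)[perm], tolerance = 1e-7)
})

# --- tuning ----------------------------------------------------------------

test_that("lambda CV returns a full finite curve and is reproducible", {
  set.seed(8)
  X <- scale(matrix(rnorm(40 * 30), 40, 30,
                    dimnames = list(NULL, paste0("c", 1:30))))
  y <- rbinom(40, 1, plogis(X[, 1] - X[, 2]))
  grid <- lambda_path(X, y, alpha = 0.5, family = "binomial", nlambda = 20)
  cv1 <- tune_lambda_cv(X, y, NULL, alpha = 1, family = "binomial",
                        folds = 5, lambda_grid = grid, seed = 3)
  cv2 <- tune_lambda_cv(X, y, NULL, alpha = 1, family = "binomial",
                        folds = 5, lambda_grid = grid, seed = 3)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_equal(nrow(cv1$cv_curve), 20)
  expect_true(all(is.finite(cv1$cv_curve$mean_error)))
  # at the top of the path everything is zero
  fit <- fit_network_lasso(X, y, NULL, alpha = 1, lam = grid[1],
                           family = "binomial")
  expect_true(all(fit == 0))
})

test_that("null phenotype drives lambda to the sparse end of the grid", {
  set.seed(9)
  X <- scale(matrix(rnorm(40 * 50), 40, 50,
                    dimnames = list(NULL, paste0("c", 1:50))))
  y <- rep(c(0, 1), 20)   # independent of X
  cv <- tune_lambda_cv(X, y, NULL, alpha = 1, family = "binomial",
                       folds = 5, seed = 1)
  fit <- fit_network_lasso(X, y, NULL, alpha = 1, lam = cv$lambda,
                           family = "binomial")
  expect_lt(mean(fit != 0), 0.10)
})

test_that("CV folds are reduced when a class is too small", {
  set.seed(10)
  X <- scale(matrix(rnorm(12 * 5), 12, 5))
  y <- c(rep(1, 3), rep(0, 9))
  expect_warning(
    cv <- tune_lambda_cv(X, y, NULL, alpha = 1, family = "binomial",
                         folds = 10, seed = 1),
    "reducing folds")
  expect_equal(cv$folds, 3)
})

# --- classification & alpha search -----------------------------------------

test_that("classify_cells sign-partitions coefficients", {
  beta <- c(a = 1, b = -1, c = 0)
  sets <- classify_cells(beta)
  expect_identical(sets, list(selected_pos = "a", selected_neg = "b",
                              background = "c"))
  empty <- classify_cells(c(a = 0, b = 0))
  expect_length(empty$selected_pos, 0)
  expect_length(empty$selected_neg, 0)
  expect_error(classify_cells(c(1, NA)), "non-finite")
})

test_that("alpha search accepts the first sufficiently sparse solution", {
  d <- small_dataset()
  norm_sc <- normalize_cells(d$sc)
  norm_bulk <- normalize_cells(d$bulk)
  genes <- intersect_genes(norm_bulk, norm_sc,
                           restrict_to = select_hvgs(norm_sc, 300))
  des <- correlation_design(norm_bulk, norm_sc, genes)
  graph <- build_cell_graph(norm_sc, k = 10)
  y <- d$phenotype$phenotype

  # cutoff 1 accepts the very first grid point
  res1 <- alpha_search(des, y, graph, alpha_grid = c(0.3, 0.6),
                       cutoff = 1.0, folds = 4)
  expect_equal(res1$alpha, 0.3)
  expect_false(res1$nonterminated)

  res <- alpha_search(des, y, graph, folds = 4)
  expect_lt(res$selected_fraction, 0.20)
  expect_equal(length(res$selected_pos) + length(res$selected_neg),
               sum(res$beta != 0))
  expect_length(intersect(res$selected_pos, res$selected_neg), 0)
  expect_identical(res$selected_pos, names(res$beta)[res$beta > 0])
  # grid validation
  expect_error(alpha_search(des, y, graph, alpha_grid = c(0.5, 0.1)),
               "ascending")
})

# --- reliability -----------------------------------------------------------

test_that("reliability test matches the textbook chi-square on a 2x2", {
  # [[30,10],[10,30]] -> chi-square 20.0 without continuity correction
  meta <- data.frame(
    cell_id = sprintf("c%03d", 1:80),
    donor_phenotype = rep(c(1, 0), each = 40))
  res <- list(selected_pos = c(sprintf("c%03d", 1:30),    # 30 pos from phen1
                               sprintf("c%03d", 41:50)),  # 10 pos from phen0
              selected_neg = c(sprintf("c%03d", 31:40),   # 10 neg from phen1
                               sprintf("c%03d", 51:80)))  # 30 neg from phen0
  rel <- reliability_test(res, meta)
  expect_equal(rel$method, "chi-square")
  expect_equal(rel$statistic, 20.0)
  expect_true(rel$direction)

  # perfectly concordant table: direction true, tiny p
  res2 <- list(selected_pos = sprintf("c%03d", 1:40),
               selected_neg = sprintf("c%03d", 41:80))
  rel2 <- reliability_test(res2, meta)
  expect_true(rel2$direction)
  expect_lt(rel2$p, 1e-10)

  # equal proportions: direction false
  res3 <- list(selected_pos = sprintf("c%03d", c(1:20, 41:60)),
               selected_neg = sprintf("c%03d", c(21:40, 61:80)))
  rel3 <- reliability_test(res3, meta)
  expect_false(rel3$direction)
  expect_error(reliability_test(list(selected_pos = character(0),
                                     selected_neg = character(0)), meta),
               "no selected cells")
})
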
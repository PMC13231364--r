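# Independent oracles used to pin expected values.  Each is a deliberately
# naive implementation (enumeration, grid search, closed form) kept apart
# from the package's own algorithms.

# cyclic coordinate-descent solver for the gaussian objective
#   (1/(2n))||y - b0 - X b||^2 + lam * (a*||b||_1 + ((1-a)/2) * b' b)
# (an elastic net; a = 1 is the plain lasso), with unpenalized intercept
oracle_cd_enet <- function(X, y, lam, a, maxit = 100000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p); b0 <- mean(y)
  xtx <- colSums(X^2) / n
  for (it in seq_len(maxit)) {
    b_old <- b; b0_old <- b0
    r <- y - b0 - X %*% b
    b0 <- b0 + mean(r)
    for (j in seq_len(p)) {
      r <- y - b0 - X %*% b
      rho <- sum(X[, j] * r) / n + xtx[j] * b[j]
      bj <- sign(rho) * max(abs(rho) - lam * a, 0) / (xtx[j] + lam * (1 - a))
      b[j] <- bj
    }
    if (max(abs(b - b_old), abs(b0 - b0_old)) < tol) break
  }
  list(beta = b, b0 = b0)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (small samples, no ties)
oracle_wilcox_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  w_obs <- sum(rank(all_v)[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2, function(idx) sum(rank(all_v)[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# weighted KS running sum evaluated step by step
oracle_gsea_es <- function(genes_ranked, scores_ranked, members,
                           exponent = 1) {
  n <- length(genes_ranked)
  inset <- genes_ranked %in% members
  k <- sum(inset)
  w <- abs(scores_ranked)^exponent
  denom <- sum(w[inset])
  running <- 0; best <- 0
  for (i in seq_len(n)) {
    running <- running +
      if (inset[i]) (if (denom > 0) w[i] / denom else 1 / k)
      else -1 / (n - k)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# ssGSEA score for one column by direct evaluation of the cumulative sums
oracle_ssgsea_col <- function(values, gene_ids, members, tau) {
  n <- length(values)
  ord <- order(-values, gene_ids)
  inset <- gene_ids[ord] %in% members
  r <- rank(values, ties.method = "average")[ord]
  w <- ifelse(inset, r^tau, 0)
  p_in <- cumsum(w) / sum(w)
  n_out <- n - sum(inset)
  p_out <- cumsum(!inset) / n_out
  sum(p_in - p_out)
}

# Breslow log partial likelihood for a single binary covariate
oracle_breslow_loglik <- function(time, event, z, beta) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(z[d_idx]) -
      length(d_idx) * log(sum(exp(beta * z[risk])))
  }
  ll
}

oracle_breslow_grid <- function(time, event, z,
                                grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, function(b) oracle_breslow_loglik(time, event, z, b), 0)
  grid[which.max(ll)]
}

# empirical survival function S(t) = P(T > t) for uncensored data
oracle_empirical_surv <- function(time, at) {
  vapply(at, function(t) mean(time > t), 0)
}

# OLS coefficients from the normal equations
oracle_ols <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# small deterministic synthetic dataset shared across tests
small_dataset <- function(seed = 7) {
  generate_paired_dataset(synth_config(
    n_genes = 400, n_cells = 600, n_bulk = 60, n_donors = 12, seed = seed))
}
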
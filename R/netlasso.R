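## Network-regularized sparse regression on the bulk-by-cell correlation
## design.  Objective, for design S (n x m), phenotype y, cell-graph
## Laplacian L:
##
##   (1/n) Loss(y, b0 + S beta)
##     + lambda * [ alpha * ||beta||_1 + ((1 - alpha)/2) * beta' L beta ]
##
## Loss is the logistic negative log-likelihood (binomial) or half squared
## error (gaussian); b0 is an unpenalized intercept.  Solved by proximal
## gradient (FISTA with backtracking and monotone restarts); the Laplacian
## quadratic sits in the smooth part, the L1 term in the proximal step.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# loss value and gradient pieces at linear predictor eta
loss_value <- function(y, eta, family) {
  if (family == "binomial") {
    # log(1 + exp(eta)) - y * eta, numerically stable
    mean(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
  } else {
    mean((y - eta)^2) / 2
  }
}

loss_residual <- function(y, eta, family) {
  if (family == "binomial") plogis(eta) - y else eta - y
}

netlasso_objective <- function(S, y, L, alpha, lam, beta, b0, family) {
  eta <- drop(S %*% beta) + b0
  pen_l1 <- lam * alpha * sum(abs(beta))
  pen_net <- if (lam * (1 - alpha) > 0) {
    lam * (1 - alpha) / 2 * sum(beta * as.numeric(L %*% beta))
  } else 0
  loss_value(y, eta, family) + pen_l1 + pen_net
}

#' Fit the network-regularized lasso on a correlation design
#'
#' Minimizes `(1/n) Loss(y, b0 + S beta) + lambda * (alpha * ||beta||_1 +
#' ((1-alpha)/2) * beta' L beta)` by proximal gradient with backtracking
#' line search (FISTA acceleration with monotone restarts).  `alpha = 1`
#' is a plain lasso; smaller `alpha` trades sparsity for smoothness of the
#' coefficients over the cell graph.
#'
#' @param design a `correlation_design` (or a plain n x m matrix).
#' @param y phenotype vector: 0/1 for `family = "binomial"`, numeric for
#'   `"gaussian"`.
#' @param graph a `cell_graph` (or any list with a `laplacian` matrix);
#'   ignored when `alpha = 1`.
#' @param alpha balance between the L1 and network penalties, in \[0, 1\].
#' @param lam overall regularization strength, >= 0.
#' @param family `"binomial"` or `"gaussian"`.
#' @param maxit,tol iteration cap and relative-objective convergence
#'   tolerance.
#' @param init optional warm start: list with `beta`, `b0`.
#' @return named per-cell coefficient vector with attributes `intercept`,
#'   `niter`, `objective`, `converged`.
#' @export
fit_network_lasso <- function(design, y, graph = NULL, alpha, lam,
                              family = c("binomial", "gaussian"),
                              maxit = 10000, tol = 1e-8, init = NULL) {
  family <- match.arg(family)
  S <- if (inherits(design, "correlation_design")) design$S else design
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lam < 0) stop("lam must be non-negative")
  n <- nrow(S); m <- ncol(S)
  if (length(y) != n) stop("length(y) does not match nrow(S)")
  if (!all(is.finite(S)) || !all(is.finite(y))) stop("non-finite entries in inputs")
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 phenotype")
  }
  net_weight <- lam * (1 - alpha)
  L <- if (net_weight > 0) {
    if (is.null(graph)) stop("a cell graph is required when alpha < 1 and lam > 0")
    lap <- if (inherits(graph, "cell_graph") || is.list(graph)) graph$laplacian else graph
    if (nrow(lap) != m) stop("Laplacian dimension does not match the design")
    lap
  } else NULL

  beta <- if (!is.null(init)) init$beta else rep(0, m)
  b0 <- if (!is.null(init)) init$b0 else {
    if (family == "binomial") qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)) else mean(y)
  }

  smooth_val <- function(beta, b0) {
    eta <- drop(S %*% beta) + b0
    v <- loss_value(y, eta, family)
    if (!is.null(L)) v <- v + net_weight / 2 * sum(beta * as.numeric(L %*% beta))
    v
  }
  smooth_grad <- function(beta, b0) {
    eta <- drop(S %*% beta) + b0
    r <- loss_residual(y, eta, family)
    g <- drop(crossprod(S, r)) / n
    if (!is.null(L)) g <- g + net_weight * as.numeric(L %*% beta)
    list(gbeta = g, gb0 = mean(r))
  }

  obj <- netlasso_objective(S, y, if (is.null(L)) 0 else L, alpha, lam,
                            beta, b0, family)
  step <- 1
  zbeta <- beta; zb0 <- b0; tk <- 1
  converged <- FALSE; it <- 0
  while (it < maxit) {
    it <- it + 1
    g <- smooth_grad(zbeta, zb0)
    fz <- smooth_val(zbeta, zb0)
    repeat {
      beta_new <- soft_threshold(zbeta - step * g$gbeta, step * lam * alpha)
      b0_new <- zb0 - step * g$gb0
      db <- beta_new - zbeta; d0 <- b0_new - zb0
      quad <- fz + sum(g$gbeta * db) + g$gb0 * d0 +
        (sum(db^2) + d0^2) / (2 * step)
      if (smooth_val(beta_new, b0_new) <= quad + 1e-12) break
      step <- step / 2
      if (step < 1e-14) break
    }
    obj_new <- netlasso_objective(S, y, if (is.null(L)) 0 else L, alpha, lam,
                                  beta_new, b0_new, family)
    if (obj_new > obj) {                     # monotone restart
      zbeta <- beta; zb0 <- b0; tk <- 1
      g <- smooth_grad(zbeta, zb0)
      beta_new <- soft_threshold(zbeta - step * g$gbeta, step * lam * alpha)
      b0_new <- zb0 - step * g$gb0
      obj_new <- netlasso_objective(S, y, if (is.null(L)) 0 else L, alpha, lam,
                                    beta_new, b0_new, family)
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zbeta <- beta_new + (tk - 1) / tk_new * (beta_new - beta)
    zb0 <- b0_new + (tk - 1) / tk_new * (b0_new - b0)
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    beta <- beta_new; b0 <- b0_new; obj <- obj_new; tk <- tk_new
    step <- step * 1.5                        # allow step to grow back
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(paste0("network-lasso solver did not converge: %d iterations, ",
                        "objective %.6g, last relative change above %.1e ",
                        "(alpha = %.3g, lambda = %.3g, family = %s)"),
                 it, obj, tol, alpha, lam, family))
  }
  names(beta) <- colnames(S)
  structure(beta, intercept = b0, niter = it, objective = obj,
            converged = converged)
}

#' KKT residual of a network-lasso solution
#'
#' Maximum violation of the subgradient optimality conditions at `beta`:
#' for zero coefficients, `max(|g_j| - lambda*alpha, 0)`; for non-zero
#' ones, `|g_j + lambda*alpha*sign(beta_j)|`, where `g` is the gradient of
#' the smooth part (loss plus Laplacian quadratic) including the intercept
#' score.
#'
#' @inheritParams fit_network_lasso
#' @param beta fitted coefficients (with `intercept` attribute, as
#'   returned by [fit_network_lasso()]).
#' @return the maximum residual (a non-negative scalar).
#' @export
kkt_residual <- function(design, y, graph = NULL, alpha, lam, beta,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  S <- if (inherits(design, "correlation_design")) design$S else design
  n <- nrow(S)
  b0 <- attr(beta, "intercept")
  if (is.null(b0)) b0 <- 0
  eta <- drop(S %*% as.numeric(beta)) + b0
  r <- loss_residual(y, eta, family)
  g <- drop(crossprod(S, r)) / n
  if (lam * (1 - alpha) > 0 && !is.null(graph)) {
    lap <- if (is.list(graph)) graph$laplacian else graph
    g <- g + lam * (1 - alpha) * as.numeric(lap %*% as.numeric(beta))
  }
  bb <- as.numeric(beta)
  viol_zero <- max(0, max(abs(g[bb == 0]) - lam * alpha, -Inf))
  viol_nz <- if (any(bb != 0)) {
    max(abs(g[bb != 0] + lam * alpha * sign(bb[bb != 0])))
  } else 0
  max(viol_zero, viol_nz, abs(mean(r)))
}

#' Regularization path grid
#'
#' `nlambda` values log-spaced from `lambda_max` (the smallest lambda at
#' which all coefficients are zero, computed from the gradient at the
#' null model) down to `min_ratio * lambda_max`.
#'
#' @inheritParams fit_network_lasso
#' @param nlambda grid length.
#' @param min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return decreasing numeric vector.
#' @export
lambda_path <- function(design, y, alpha, family = c("binomial", "gaussian"),
                        nlambda = 50, min_ratio = 0.01) {
  family <- match.arg(family)
  S <- if (inherits(design, "correlation_design")) design$S else design
  n <- nrow(S)
  mu0 <- if (family == "binomial") mean(y) else mean(y)
  r0 <- if (family == "binomial") rep(mean(y), n) - y else mean(y) - y
  lmax <- max(abs(drop(crossprod(S, r0)) / n)) / max(alpha, 1e-3)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Choose lambda by cross-validation
#'
#' K-fold cross-validation (stratified by `y` for the binomial family)
#' over a lambda path fitted with warm starts; the selected lambda
#' minimizes the mean held-out error (binomial deviance or MSE), with
#' ties resolved toward the larger (sparser) lambda.
#'
#' @inheritParams fit_network_lasso
#' @param folds number of folds (>= 2); reduced with a warning if a class
#'   has fewer members than folds.
#' @param lambda_grid optional decreasing lambda grid; default
#'   [lambda_path()] on the full data.
#' @param seed fold-assignment seed (recorded in the result).
#' @return list with `lambda` (the minimizer), `cv_curve` (data.frame:
#'   lambda, mean_error, se_error), `folds`, `seed`.
#' @export
tune_lambda_cv <- function(design, y, graph = NULL, alpha,
                           family = c("binomial", "gaussian"),
                           folds = 10, lambda_grid = NULL, seed = 42L) {
  family <- match.arg(family)
  S <- if (inherits(design, "correlation_design")) design$S else design
  n <- nrow(S)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  if (family == "binomial") {
    min_class <- min(table(y))
    if (min_class < 2) stop("binomial CV needs at least 2 samples per class")
    if (min_class < folds) {
      warning("reducing folds from ", folds, " to ", min_class,
              " so every fold sees both classes")
      folds <- min_class
    }
  }
  if (is.null(lambda_grid)) {
    lambda_grid <- lambda_path(design, y, alpha, family)
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold_id <- integer(n)
  if (family == "binomial") {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id <- sample(rep_len(seq_len(folds), n))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  err <- matrix(NA_real_, length(lambda_grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    init <- NULL
    for (li in seq_along(lambda_grid)) {
      fit <- fit_network_lasso(S[tr, , drop = FALSE], y[tr], graph,
                               alpha, lambda_grid[li], family, init = init)
      init <- list(beta = as.numeric(fit), b0 = attr(fit, "intercept"))
      eta <- drop(S[te, , drop = FALSE] %*% as.numeric(fit)) + attr(fit, "intercept")
      err[li, f] <- if (family == "binomial") {
        mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
        -2 * mean(y[te] * log(mu) + (1 - y[te]) * log(1 - mu))
      } else mean((y[te] - eta)^2)
    }
  }
  mean_err <- rowMeans(err)
  se_err <- apply(err, 1, sd) / sqrt(folds)
  best <- which(mean_err <= min(mean_err) + 1e-12)[1]  # ties -> larger lambda
  list(lambda = lambda_grid[best],
       cv_curve = data.frame(lambda = lambda_grid, mean_error = mean_err,
                             se_error = se_err),
       folds = folds, seed = seed)
}

#' Sign-partition coefficients into selected cell sets
#'
#' @param beta named per-cell coefficient vector.
#' @return list with `selected_pos` (beta > 0), `selected_neg` (beta < 0)
#'   and `background` (beta == 0) cell-id vectors.
#' @export
classify_cells <- function(beta) {
  if (!all(is.finite(beta))) stop("non-finite coefficients")
  ids <- names(beta)
  if (is.null(ids)) ids <- as.character(seq_along(beta))
  list(selected_pos = ids[beta > 0],
       selected_neg = ids[beta < 0],
       background = ids[beta == 0])
}

#' Search alpha until the selection is sparse enough
#'
#' Iterates an ascending alpha grid; at each alpha, lambda is chosen by
#' [tune_lambda_cv()] and the model refitted at the minimizer on the full
#' data.  The first alpha whose selected-cell fraction falls below
#' `cutoff` is accepted (the termination rule); if none qualifies, the
#' alpha with the smallest selected fraction is returned and flagged.
#'
#' @inheritParams tune_lambda_cv
#' @param alpha_grid ascending grid within \[0, 1\]; default 0.05 to 0.90
#'   in steps of 0.05.
#' @param cutoff maximum admissible selected fraction, default 0.20.
#' @return a `scissor_result`: list with `beta`, `selected_pos`,
#'   `selected_neg`, `alpha`, `lambda`, `cv_curve`, `selected_fraction`,
#'   `family`, `nonterminated`, `search` (per-alpha diagnostics),
#'   `cv_seed`.
#' @export
alpha_search <- function(design, y, graph,
                         alpha_grid = seq(0.05, 0.90, by = 0.05),
                         cutoff = 0.20, family = c("binomial", "gaussian"),
                         folds = 10, lambda_grid = NULL, cv_seed = 42L) {
  family <- match.arg(family)
  if (is.unsorted(alpha_grid) || any(alpha_grid < 0) || any(alpha_grid > 1)) {
    stop("alpha_grid must be ascending within [0, 1]")
  }
  S <- if (inherits(design, "correlation_design")) design$S else design
  m <- ncol(S)
  search <- data.frame(alpha = numeric(0), lambda = numeric(0),
                       selected_fraction = numeric(0))
  best <- NULL
  for (a in alpha_grid) {
    cv <- tune_lambda_cv(design, y, graph, a, family, folds = folds,
                         lambda_grid = lambda_grid, seed = cv_seed)
    fit <- fit_network_lasso(design, y, graph, a, cv$lambda, family)
    sets <- classify_cells(fit)
    frac <- (length(sets$selected_pos) + length(sets$selected_neg)) / m
    search <- rbind(search, data.frame(alpha = a, lambda = cv$lambda,
                                       selected_fraction = frac))
    cand <- list(beta = fit, sets = sets, alpha = a, cv = cv, fraction = frac)
    if (is.null(best) || frac < best$fraction) best <- cand
    if (frac < cutoff) { best <- cand; break }
  }
  nonterminated <- best$fraction >= cutoff
  if (nonterminated) {
    warning("no alpha reached a selected fraction below ", cutoff,
            "; returning the sparsest solution (alpha = ", best$alpha, ")")
  }
  structure(list(beta = best$beta,
                 selected_pos = best$sets$selected_pos,
                 selected_neg = best$sets$selected_neg,
                 alpha = best$alpha, lambda = best$cv$lambda,
                 cv_curve = best$cv$cv_curve,
                 selected_fraction = best$fraction,
                 family = family, nonterminated = nonterminated,
                 search = search, cv_seed = cv_seed),
            class = "scissor_result")
}

#' @export
print.scissor_result <- function(x, ...) {
  cat(sprintf(paste0("<scissor_result> alpha = %.2f, lambda = %.4g, ",
                     "%d positive / %d negative cells (%.1f%% selected)%s\n"),
              x$alpha, x$lambda, length(x$selected_pos),
              length(x$selected_neg), 100 * x$selected_fraction,
              if (x$nonterminated) " [non-terminated]" else ""))
  invisible(x)
}

#' Reliability check of the selected sets against donor phenotype
#'
#' Cross-tabulates donor phenotype against the selected set (positive vs
#' negative) over the selected cells; tests independence by chi-square
#' (without continuity correction) or Fisher's exact test when any
#' expected count is below 5.  The direction flag is TRUE when cells from
#' phenotype-1 donors have the higher proportion of positively selected
#' cells, i.e. the selection is concordant with the donor phenotype.
#'
#' @param result a `scissor_result` (or list with `selected_pos`,
#'   `selected_neg`).
#' @param cell_meta data.frame with `cell_id` and `donor_phenotype`.
#' @return list with `table` (2 x 2), `statistic`, `p`, `method`,
#'   `direction`.
#' @export
reliability_test <- function(result, cell_meta) {
  sel <- c(result$selected_pos, result$selected_neg)
  if (length(sel) == 0) stop("no selected cells")
  phen <- setNames(cell_meta$donor_phenotype, cell_meta$cell_id)
  if (!all(sel %in% names(phen))) stop("selected cells missing donor phenotype")
  set_lab <- factor(rep(c("pos", "neg"),
                        c(length(result$selected_pos),
                          length(result$selected_neg))),
                    levels = c("pos", "neg"))
  don_lab <- factor(phen[sel], levels = c(1, 0),
                    labels = c("phenotype1", "phenotype0"))
  tab <- table(don_lab, set_lab)
  prop_pos <- prop.table(tab, 1)[, "pos"]
  direction <- is.finite(prop_pos[1]) && is.finite(prop_pos[2]) &&
    prop_pos["phenotype1"] > prop_pos["phenotype0"]
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, statistic = NA_real_, p = NA_real_,
                method = "degenerate", direction = direction))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    list(table = tab, statistic = NA_real_, p = ft$p.value,
         method = "fisher", direction = direction)
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
         method = "chi-square", direction = direction)
  }
}
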
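## Top-fold-change gene signature, median-split scoring, and survival
## quantification (Kaplan-Meier + log-rank; stage-adjusted Cox).

#' Build a gene signature from a DE table
#'
#' The `n` genes with the largest fold change among genes flagged
#' significant, ties broken by smaller FDR then gene id.  If fewer than
#' `n` genes are significant, all of them are returned with a warning.
#'
#' @param de a `de_table` from [wilcoxon_de()].
#' @param n signature size, default 50.
#' @param name signature name.
#' @return a [gene_set()] (possibly empty `members` only if no gene is
#'   significant, in which case an empty-set error is avoided by
#'   returning a zero-length list with a warning).
#' @export
build_signature <- function(de, n = 50, name = "signature") {
  stopifnot(is.data.frame(de), nrow(de) > 0)
  sig <- de[de$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant genes; returning an empty signature")
    return(structure(list(name = name, members = character(0), note = ""),
                     class = "gene_set"))
  }
  sig <- sig[order(-sig$fc, sig$fdr, sig$gene_id), , drop = FALSE]
  if (nrow(sig) < n) {
    warning("only ", nrow(sig), " significant genes available (requested ",
            n, ")")
    n <- nrow(sig)
  }
  gene_set(name, sig$gene_id[seq_len(n)],
           note = sprintf("top-%d fold-change signature", n))
}

#' Split samples at the median score
#'
#' `high` for scores strictly above the median; scores equal to the
#' median go to `low` (a deterministic tie rule).
#'
#' @param scores named numeric vector (>= 2 samples).
#' @return named factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  if (length(unique(as.numeric(scores))) == 1) {
    stop("all scores identical: degenerate median split")
  }
  med <- median(as.numeric(scores))
  setNames(factor(ifelse(as.numeric(scores) > med, "high", "low"),
                  levels = c("low", "high")),
           names(scores))
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit estimator per group and the 1-df log-rank chi-square.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param groups two-level grouping vector.
#' @return list with `km` (data.frame: group, time, surv, n_risk,
#'   n_event), `chisq`, `logrank_p`.
#' @export
km_logrank <- function(time, event, groups) {
  if (any(time < 0)) stop("negative times")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two non-empty groups required")
  if (any(table(groups) == 0)) stop("zero-size group")
  fit <- survfit(Surv(time, event) ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(group = sub("^groups=", "", strata),
                   time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    # no events anywhere: curves are flat and the test is undefined
    return(list(km = km, chisq = NA_real_, logrank_p = NA_real_))
  }
  sd <- survdiff(Surv(time, event) ~ groups)
  chisq <- unname(sd$chisq)
  list(km = km, chisq = chisq, logrank_p = 1 - stats::pchisq(chisq, df = 1))
}

#' Stage-adjusted proportional-hazards fit for a score group
#'
#' Cox partial-likelihood maximization (Breslow tie handling by default)
#' of `Surv(time, event) ~ score_group (+ stage)`.  The hazard ratio is
#' for the second level of `score_group` (high vs low under
#' [median_split()] coding), with a Wald 95% CI and p value.  Monotone
#' likelihood / non-convergence (complete separation) is flagged rather
#' than silently reported.
#'
#' @param time,event survival outcome.
#' @param score_group two-level factor (reference level first).
#' @param stage optional covariate to adjust for (e.g. early/late).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `hr`, `ci_low`, `ci_high`, `cox_p`, `coef`, `se`,
#'   `flagged`, `covariates`.
#' @export
cox_fit <- function(time, event, score_group, stage = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  score_group <- as.factor(score_group)
  if (nlevels(droplevels(score_group)) < 2) {
    stop("score_group is constant: coefficient undefined")
  }
  if (sum(event) < 2) stop("need at least 2 events")
  df <- data.frame(time = time, event = event, score_group = score_group)
  form <- Surv(time, event) ~ score_group
  covariates <- "score_group"
  if (!is.null(stage)) {
    df$stage <- as.factor(stage)
    form <- Surv(time, event) ~ score_group + stage
    covariates <- c("score_group", "stage")
  }
  fit <- coxph(form, data = df, ties = ties)
  idx <- grep("^score_group", names(coef(fit)))[1]
  b <- coef(fit)[idx]
  se <- sqrt(diag(vcov(fit)))[idx]
  flagged <- !is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 100
  z <- b / se
  list(hr = unname(exp(b)),
       ci_low = unname(exp(b - 1.96 * se)),
       ci_high = unname(exp(b + 1.96 * se)),
       cox_p = unname(2 * stats::pnorm(-abs(z))),
       coef = unname(b), se = unname(se),
       flagged = flagged, covariates = covariates)
}

#' Score a signature on bulk samples and quantify survival differences
#'
#' Convenience wrapper: ssGSEA-score the signature on the bulk matrix,
#' split at the median, then run [km_logrank()] and [cox_fit()]
#' (stage-adjusted when a `stage` column is present).
#'
#' @param bulk an [expression_matrix()] of the bulk cohort.
#' @param signature a [gene_set()].
#' @param pheno phenotype table with `sample_id`, `time`, `event` and
#'   optionally `stage`.
#' @param tau ssGSEA weighting exponent.
#' @return list with `scores`, `groups`, `km` (from [km_logrank()]),
#'   `cox` (from [cox_fit()]).
#' @export
signature_survival <- function(bulk, signature, pheno, tau = 0.25) {
  validate_phenotype(pheno)
  if (!all(c("time", "event") %in% names(pheno))) {
    stop("phenotype table needs time and event columns")
  }
  scores <- ssgsea_score(bulk, signature, tau = tau)
  scores <- scores[pheno$sample_id]
  groups <- median_split(scores)
  km <- km_logrank(pheno$time, pheno$event, groups)
  cox <- cox_fit(pheno$time, pheno$event, groups,
                 stage = if ("stage" %in% names(pheno)) pheno$stage else NULL)
  list(scores = scores, groups = groups, km = km, cox = cox)
}
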
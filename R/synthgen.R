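#' Configuration for the paired-cohort simulator
#'
#' Defines the study conditions of the simulated bulk + single-cell
#' cohort: a bulk RNA-seq cohort with a binary phenotype (e.g. smoker vs
#' never-smoker), staged survival outcomes, and a single-cell compartment
#' of discrete cell types of which some subtypes are truly associated with
#' the phenotype.  Associated subtypes carry a planted expression program
#' (`program_size` genes shifted by `effect_log2fc`) and are
#' over-represented both among cells of matching-phenotype donors and in
#' the cell-type mixing weights of matching-phenotype bulk samples
#' (`enrichment_shift`).
#'
#' @param n_genes,n_celltypes,n_cells,n_bulk,n_donors problem sizes.
#' @param phenotype_balance fraction of bulk samples (and donors) with
#'   phenotype = 1; default 0.34, a typical smoker fraction in an East
#'   Asian lung adenocarcinoma cohort.
#' @param celltype_props baseline cell-type proportions (sum to 1).
#' @param assoc_subtypes integer vector in {+1, -1, 0} per cell type:
#'   planted association direction.  Default: one +1 subtype at 15%
#'   baseline prevalence and one -1 subtype at 15%.
#' @param marker_size marker genes per cell type (4-fold up in that type),
#'   giving types distinct profiles.
#' @param program_size genes per planted phenotype program.
#' @param effect_log2fc planted log2 fold change on program genes in the
#'   associated subtypes.
#' @param nb_dispersion negative-binomial size parameter theta for
#'   single-cell counts (variance mu + mu^2/theta).
#' @param bulk_dispersion NB size parameter for bulk counts (bulk is less
#'   overdispersed than single cells).
#' @param libsize_range min/max single-cell library size (uniform draw).
#' @param bulk_libsize expected bulk library size.
#' @param mixing_concentration Dirichlet concentration for the per-sample
#'   cell-type mixing weights (larger = tighter around `celltype_props`).
#' @param enrichment_shift additive weight shift of the matching-direction
#'   subtypes in matching-phenotype bulk samples (and, at the donor level,
#'   in matching-phenotype donors' cell-type proportions).
#' @param surv_baseline_scale baseline expected survival time (days) under
#'   an exponential hazard.
#' @param surv_effect log-hazard increase per SD of the planted signature
#'   level (the +1-subtype mixing weight).
#' @param censor_rate target fraction of censored bulk samples.
#' @param stage_assoc correlation of the latent late-stage propensity with
#'   the signature level, so that stage is a genuine confounder for the
#'   Cox adjustment.
#' @param batch_shift SD of a per-gene log-normal batch offset applied to
#'   half the cells; 0 (default) disables the batch structure.
#' @param dosage also emit a continuous smoking-dosage column (pack-years
#'   style, log-normal among phenotype-1 donors/samples).
#' @param seed integer seed; the generator is fully deterministic given it.
#'
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 1200, n_celltypes = 5, n_cells = 3000,
                         n_bulk = 120, n_donors = 20,
                         phenotype_balance = 0.34,
                         celltype_props = c(0.15, 0.15, 0.30, 0.25, 0.15),
                         assoc_subtypes = c(1L, -1L, 0L, 0L, 0L),
                         marker_size = 25, program_size = 80,
                         effect_log2fc = 1, nb_dispersion = 2,
                         bulk_dispersion = 20,
                         libsize_range = c(2000, 10000),
                         bulk_libsize = 3e5,
                         mixing_concentration = 50,
                         enrichment_shift = 0.10,
                         surv_baseline_scale = 1000, surv_effect = 1,
                         censor_rate = 0.3, stage_assoc = 0.4,
                         batch_shift = 0, dosage = FALSE, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_celltypes = n_celltypes,
              n_cells = n_cells, n_bulk = n_bulk, n_donors = n_donors,
              phenotype_balance = phenotype_balance,
              celltype_props = celltype_props,
              assoc_subtypes = as.integer(assoc_subtypes),
              marker_size = marker_size, program_size = program_size,
              effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
              bulk_dispersion = bulk_dispersion,
              libsize_range = libsize_range, bulk_libsize = bulk_libsize,
              mixing_concentration = mixing_concentration,
              enrichment_shift = enrichment_shift,
              surv_baseline_scale = surv_baseline_scale,
              surv_effect = surv_effect, censor_rate = censor_rate,
              stage_assoc = stage_assoc, batch_shift = batch_shift,
              dosage = dosage, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_genes", "n_celltypes", "n_cells", "n_bulk", "n_donors",
              "marker_size", "program_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1) stop(f, " must be a positive count")
  }
  if (cfg$phenotype_balance <= 0 || cfg$phenotype_balance >= 1) {
    stop("phenotype_balance must lie in (0, 1)")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (length(cfg$celltype_props) != cfg$n_celltypes ||
      abs(sum(cfg$celltype_props) - 1) > 1e-8) {
    stop("celltype_props must have length n_celltypes and sum to 1")
  }
  if (length(cfg$assoc_subtypes) != cfg$n_celltypes ||
      !all(cfg$assoc_subtypes %in% c(-1L, 0L, 1L))) {
    stop("assoc_subtypes must be a vector in {-1, 0, +1} per cell type")
  }
  need <- sum(cfg$assoc_subtypes == 0L) * cfg$marker_size +
    2 * cfg$program_size
  if (need > cfg$n_genes) {
    stop("n_genes too small for marker and program blocks (need >= ", need, ")")
  }
  if (cfg$libsize_range[1] <= 0 || cfg$libsize_range[2] < cfg$libsize_range[1]) {
    stop("invalid libsize_range")
  }
  invisible(cfg)
}

# shift cell-type proportions toward the matching-direction subtypes,
# then renormalize; used both for donor compositions and bulk weights
shift_props <- function(base, assoc, phen, shift) {
  w <- base
  dir <- if (phen == 1) 1L else -1L
  idx <- which(assoc == dir)
  if (length(idx) > 0 && shift > 0) w[idx] <- w[idx] + shift / length(idx)
  w / sum(w)
}

#' Generate a paired bulk + single-cell dataset with planted truth
#'
#' Single-cell counts are negative-binomial around cell-type mean
#' profiles; program genes are shifted by `effect_log2fc` in associated
#' subtypes.  Bulk counts are NB around per-sample mixtures of the same
#' cell-type mean profiles, with Dirichlet mixing weights whose
#' matching-direction component is shifted by `enrichment_shift` in
#' matching-phenotype samples.  Survival times follow an exponential
#' hazard multiplied by `exp(surv_effect * z)` where `z` is the
#' standardized +1-subtype weight of the sample; stage is binary with
#' latent correlation `stage_assoc` to `z`.  Fully deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with elements `bulk` ([expression_matrix()], counts),
#'   `phenotype` (data.frame: sample_id, phenotype, dosage?, stage, time,
#'   event, batch), `sc` ([expression_matrix()], counts), `cell_meta`
#'   (data.frame: cell_id, donor, donor_phenotype, cell_type, batch), and
#'   `truth` (class `ground_truth`: `cell_assoc` named vector in
#'   {-1, 0, +1}, `program_genes_pos`, `program_genes_neg`,
#'   `bulk_weights` with rows summing to 1, `subtype_assoc`).
#' @export
generate_paired_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; nt <- config$n_celltypes
  nc <- config$n_cells; nb <- config$n_bulk
  gene_ids <- sprintf("G%05d", seq_len(ng))
  type_ids <- sprintf("T%02d", seq_len(nt))

  # gene blocks: marker blocks for the unassociated types, then the two
  # program blocks; an associated subtype is distinguished by its program,
  # so program genes are the genes that separate it from the background
  bg_types <- which(config$assoc_subtypes == 0L)
  marker_idx <- split(seq_len(length(bg_types) * config$marker_size),
                      rep(seq_along(bg_types), each = config$marker_size))
  names(marker_idx) <- as.character(bg_types)
  off <- length(bg_types) * config$marker_size
  prog_pos <- seq(off + 1, off + config$program_size)
  prog_neg <- seq(off + config$program_size + 1, off + 2 * config$program_size)

  base <- rlnorm(ng, meanlog = 0, sdlog = 1)
  base <- base / sum(base)                       # relative expression
  profiles <- matrix(base, ng, nt, dimnames = list(gene_ids, type_ids))
  for (t in bg_types) {
    idx <- marker_idx[[as.character(t)]]
    profiles[idx, t] <- profiles[idx, t] * 4
  }
  mult <- 2^config$effect_log2fc
  pos_types <- which(config$assoc_subtypes == 1L)
  neg_types <- which(config$assoc_subtypes == -1L)
  if (config$effect_log2fc != 0 &&
      (length(pos_types) == 0 || length(neg_types) == 0)) {
    stop("an associated program is planted but a direction has no subtype")
  }
  for (t in pos_types) profiles[prog_pos, t] <- profiles[prog_pos, t] * mult
  for (t in neg_types) profiles[prog_neg, t] <- profiles[prog_neg, t] * mult

  # donors and cells
  n1 <- round(config$n_donors * config$phenotype_balance)
  donor_phen <- sample(c(rep(1L, n1), rep(0L, config$n_donors - n1)))
  donor_ids <- sprintf("D%02d", seq_len(config$n_donors))
  cell_donor <- sample(seq_len(config$n_donors), nc, replace = TRUE)
  cell_type <- integer(nc)
  for (d in seq_len(config$n_donors)) {
    idx <- which(cell_donor == d)
    pr <- shift_props(config$celltype_props, config$assoc_subtypes,
                      donor_phen[d], config$enrichment_shift)
    cell_type[idx] <- sample(seq_len(nt), length(idx), replace = TRUE, prob = pr)
  }
  libsizes <- round(runif(nc, config$libsize_range[1], config$libsize_range[2]))
  mu_sc <- profiles[, cell_type, drop = FALSE] *
    rep(libsizes, each = ng)
  if (config$batch_shift > 0) {
    batch <- rep_len(c(1L, 2L), nc)
    gene_off <- rlnorm(ng, 0, config$batch_shift)
    mu_sc[, batch == 2L] <- mu_sc[, batch == 2L] * gene_off
  } else {
    batch <- rep(1L, nc)
  }
  sc_counts <- matrix(rnbinom(ng * nc, mu = as.vector(mu_sc),
                              size = config$nb_dispersion), ng, nc)
  cell_ids <- sprintf("C%05d", seq_len(nc))
  dimnames(sc_counts) <- list(gene_ids, cell_ids)

  # bulk: Dirichlet mixing weights over cell types, shifted by phenotype
  nb1 <- round(nb * config$phenotype_balance)
  bulk_phen <- sample(c(rep(1L, nb1), rep(0L, nb - nb1)))
  sample_ids <- sprintf("S%03d", seq_len(nb))
  wmat <- matrix(0, nb, nt, dimnames = list(sample_ids, type_ids))
  for (i in seq_len(nb)) {
    g <- rgamma(nt, shape = config$mixing_concentration * config$celltype_props)
    w <- g / sum(g)
    wmat[i, ] <- shift_props(w, config$assoc_subtypes, bulk_phen[i],
                             config$enrichment_shift)
  }
  bulk_mu <- (profiles %*% t(wmat)) * config$bulk_libsize
  bulk_counts <- matrix(rnbinom(ng * nb, mu = as.vector(bulk_mu),
                                size = config$bulk_dispersion), ng, nb)
  dimnames(bulk_counts) <- list(gene_ids, sample_ids)

  # survival and stage driven by the +1-subtype weight
  sig_level <- if (length(pos_types) > 0) rowSums(wmat[, pos_types, drop = FALSE])
               else rep(0, nb)
  z <- if (sd(sig_level) > 0) as.vector(scale(sig_level)) else rep(0, nb)
  rate <- exp(config$surv_effect * z) / config$surv_baseline_scale
  t_event <- rexp(nb, rate = rate)
  if (config$censor_rate > 0) {
    r_c <- mean(rate) * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(nb, rate = r_c)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, nb)
  }
  rho <- config$stage_assoc
  latent <- rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(nb)
  stage <- ifelse(latent > median(latent), "late", "early")
  dosage_col <- if (config$dosage) {
    ifelse(bulk_phen == 1, round(rlnorm(nb, log(20), 0.5), 1), 0)
  } else NULL

  pheno <- data.frame(sample_id = sample_ids, phenotype = bulk_phen,
                      stage = stage, time = round(time, 2), event = event,
                      batch = "cohort1", stringsAsFactors = FALSE)
  if (!is.null(dosage_col)) pheno$dosage <- dosage_col

  cell_meta <- data.frame(cell_id = cell_ids,
                          donor = donor_ids[cell_donor],
                          donor_phenotype = donor_phen[cell_donor],
                          cell_type = type_ids[cell_type],
                          batch = batch, stringsAsFactors = FALSE)

  truth <- structure(list(
    cell_assoc = setNames(config$assoc_subtypes[cell_type], cell_ids),
    program_genes_pos = gene_ids[prog_pos],
    program_genes_neg = gene_ids[prog_neg],
    bulk_weights = wmat,
    subtype_assoc = setNames(config$assoc_subtypes, type_ids),
    signature_level = setNames(sig_level, sample_ids)
  ), class = "ground_truth")

  list(bulk = expression_matrix(bulk_counts, layer = "counts"),
       phenotype = pheno,
       sc = expression_matrix(sc_counts, layer = "counts"),
       cell_meta = cell_meta,
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Single-cell counts go to an MTX directory (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`); bulk matrix, phenotype table and cell
#' metadata to TSV; ground truth to JSON.
#'
#' @param dataset output of [generate_paired_dataset()].
#' @param out_dir output directory (created if missing).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bulk = file.path(out_dir, "bulk_counts.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    sc = file.path(out_dir, "sc_counts"),
    cell_meta = file.path(out_dir, "cell_metadata.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_matrix(dataset$bulk, paths["bulk"], "tsv")
  write.table(dataset$phenotype, paths["phenotype"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix(dataset$sc, paths["sc"], "mtx")
  write.table(dataset$cell_meta, paths["cell_meta"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(list(
    cell_assoc = as.list(tr$cell_assoc),
    program_genes_pos = tr$program_genes_pos,
    program_genes_neg = tr$program_genes_neg,
    bulk_weights = as.data.frame(tr$bulk_weights),
    subtype_assoc = as.list(tr$subtype_assoc)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Recovery metrics of a selection against the planted truth
#'
#' For each direction, precision = |selected intersect truth| / |selected|,
#' recall = |selected intersect truth| / |truth|, and balanced accuracy =
#' (sensitivity + specificity) / 2 over all cells.  An empty selected set
#' yields `precision = NA` with `empty = TRUE` and recall 0.
#'
#' @param result a `scissor_result` (or any list with `selected_pos` and
#'   `selected_neg` cell-id vectors).
#' @param truth a `ground_truth` (or any list with a named `cell_assoc`
#'   vector in {-1, 0, +1}).
#' @return data.frame with one row per direction (`pos`, `neg`).
#' @export
truth_evaluation <- function(result, truth) {
  assoc <- truth$cell_assoc
  universe <- names(assoc)
  sel <- list(pos = result$selected_pos, neg = result$selected_neg)
  if (!all(unlist(sel) %in% universe)) {
    stop("selected cell identifiers not found in the truth universe")
  }
  rows <- lapply(c(pos = 1L, neg = -1L), function(dir) {
    s <- if (dir == 1L) sel$pos else sel$neg
    truth_set <- universe[assoc == dir]
    tp <- length(intersect(s, truth_set))
    empty <- length(s) == 0
    precision <- if (empty) NA_real_ else tp / length(s)
    recall <- if (length(truth_set) == 0) NA_real_ else tp / length(truth_set)
    tn <- length(setdiff(setdiff(universe, truth_set), s))
    spec <- if (length(truth_set) == length(universe)) NA_real_
            else tn / (length(universe) - length(truth_set))
    bacc <- mean(c(if (is.na(recall)) NULL else recall,
                   if (is.na(spec)) NULL else spec))
    data.frame(n_selected = length(s), n_truth = length(truth_set),
               precision = precision, recall = if (is.na(recall)) 0 else recall,
               balanced_accuracy = bacc, empty = empty)
  })
  out <- do.call(rbind, rows)
  out <- cbind(direction = c("pos", "neg"), out)
  rownames(out) <- NULL
  out
}
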
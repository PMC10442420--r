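# Bundled synthetic multi-omics study.  The defaults define the study
# conditions used throughout the test-suite and the reproduction script:
# a desk-scale cohort with Hardy-Weinberg genotypes in LD blocks, genes with
# allelic heterogeneity (up to 3 independent cis signals), one pleiotropic
# variant driving several genes, a cis-regulated transcription-factor-like
# mediator with distal targets, a protein layer partially coupled to its
# cognate genes, a metabolite layer and sex/center/genotype-PC covariates.

#' Simulate a complete synthetic multi-omics study
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of gene-expression phenotypes (spread over
#'   \code{n_chrom} chromosomes).
#' @param n_proteins Number of proteins; each is coupled to a cognate gene
#'   with slope \code{protein_coupling}.
#' @param n_metabolites Number of (unanchored) metabolites.
#' @param n_chrom Number of chromosomes.
#' @param snps_per_gene Variants in each gene's cis block neighbourhood.
#' @param cis_beta Planted cis effect size (phenotype-SD units per
#'   standardized allele).
#' @param frac_cis_genes Fraction of genes given at least one cis signal.
#' @param protein_coupling Gene-to-protein path slope.
#' @param protein_missing_rate MCAR protein missingness (<= 0.085).
#' @param seed Integer seed; everything derives from it.
#' @return List: \code{genotypes}, \code{phenos}, \code{covariates},
#'   \code{truth} (planted effects and labels).
#' @export
simulate_study <- function(n_samples = 500, n_genes = 30, n_proteins = 10,
                           n_metabolites = 8, n_chrom = 2,
                           snps_per_gene = 6, cis_beta = 0.8,
                           frac_cis_genes = 0.5, protein_coupling = 0.6,
                           protein_missing_rate = 0.05, seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  # variant map: one LD block of snps_per_gene variants near each gene TSS
  gene_chrom <- rep(seq_len(n_chrom), length.out = n_genes)
  gene_tss <- unlist(lapply(seq_len(n_chrom), function(ch) {
    k <- sum(gene_chrom == ch)
    seq(2e6, by = 12e6, length.out = k)
  }))[order(order(gene_chrom))]
  specs <- list()
  for (g in seq_len(n_genes)) {
    maf <- round(runif(1, 0.1, 0.5), 3)
    pos <- sort(gene_tss[g] + sample(seq(-8e5, 8e5, by = 1e3),
                                     snps_per_gene))
    specs[[g]] <- variant_specs(
      sprintf("rs_g%02d_%d", g, seq_len(snps_per_gene)),
      as.character(gene_chrom[g]), pos,
      maf = rep(maf, snps_per_gene),
      block_id = g, block_r2 = 0.9)
  }
  specs <- do.call(rbind, specs)
  # break blocks into sub-blocks so genes can carry independent signals:
  # every third variant is unlinked (its own block id)
  unlink_idx <- seq(3, nrow(specs), by = 3)
  specs$block_id[unlink_idx] <- n_genes + seq_along(unlink_idx)
  genotypes <- simulate_genotypes(specs, n_samples, seed = seed + 1L)

  gene_ids <- sprintf("GENE%02d", seq_len(n_genes))
  prot_ids <- sprintf("PROT%02d", seq_len(n_proteins))
  met_ids <- sprintf("MET%02d", seq_len(n_metabolites))
  prot_gene <- gene_ids[seq_len(n_proteins)]
  meta <- rbind(
    data.frame(phenotype_id = gene_ids, type = "gene",
               chrom = as.character(gene_chrom), tss = gene_tss,
               group_id = NA, strand = sample(c("+", "-"), n_genes, TRUE),
               stringsAsFactors = FALSE),
    data.frame(phenotype_id = prot_ids, type = "protein",
               chrom = as.character(gene_chrom[seq_len(n_proteins)]),
               tss = gene_tss[seq_len(n_proteins)], group_id = NA,
               strand = NA, stringsAsFactors = FALSE),
    data.frame(phenotype_id = met_ids, type = "metabolite", chrom = NA,
               tss = NA, group_id = NA, strand = NA,
               stringsAsFactors = FALSE))

  eff <- list()
  cis_genes <- gene_ids[seq_len(ceiling(frac_cis_genes * n_genes))]
  n_sig <- rep_len(c(1L, 2L, 3L), length(cis_genes))   # allelic heterogeneity
  for (i in seq_along(cis_genes)) {
    g <- match(cis_genes[i], gene_ids)
    block_snps <- sprintf("rs_g%02d_%d", g, c(1L, 3L, 6L))[seq_len(n_sig[i])]
    eff[[length(eff) + 1L]] <- planted_effects(
      rep(cis_genes[i], n_sig[i]), block_snps,
      beta = cis_beta * c(1, 0.8, 0.7)[seq_len(n_sig[i])], mode = "cis")
  }
  # pleiotropy: the first gene's lead variant also drives genes 2 and 3
  # directly, gene 3 with opposite sign
  if (n_genes >= 3) {
    eff[[length(eff) + 1L]] <- planted_effects(
      c(gene_ids[2], gene_ids[3]), rep("rs_g01_1", 2),
      beta = c(0.5, -0.5), mode = "trans_direct")
  }
  # trans: gene 1 acts as a cis-regulated mediator (TF-like) for distal
  # genes on the other chromosome
  targets <- gene_ids[gene_chrom != gene_chrom[1]]
  targets <- utils::tail(targets, 3)
  eff[[length(eff) + 1L]] <- planted_effects(
    targets, rep("rs_g01_1", length(targets)), beta = 0.4,
    mode = "trans_mediated", mediator_id = gene_ids[1])
  # proteins follow their cognate gene
  eff[[length(eff) + 1L]] <- planted_effects(
    prot_ids, rep("rs_g01_1", n_proteins), beta = protein_coupling,
    mode = "trans_mediated", mediator_id = prot_gene)
  # two metabolites get a direct genetic effect
  if (n_metabolites >= 2) {
    eff[[length(eff) + 1L]] <- planted_effects(
      met_ids[1:2], c("rs_g02_1", "rs_g04_1"), beta = 0.6,
      mode = "trans_direct")
  }
  effects <- do.call(rbind, eff)
  # fix the protein "mediated" rows: the variant bookkeeping should name the
  # cognate gene's own lead, not rs_g01_1
  pr <- effects$phenotype_id %in% prot_ids
  effects$variant_id[pr] <- sprintf("rs_g%02d_1",
                                    match(effects$mediator_id[pr], gene_ids))

  covariates <- cbind(
    sex = rbinom(n_samples, 1, 0.5),
    center = sample(0:2, n_samples, TRUE),
    gpc1 = rnorm(n_samples), gpc2 = rnorm(n_samples),
    gpc3 = rnorm(n_samples))
  rownames(covariates) <- rownames(genotypes$dosage)
  loadings <- matrix(rnorm(ncol(covariates) * nrow(meta), sd = 0.15),
                     ncol(covariates), nrow(meta),
                     dimnames = list(colnames(covariates),
                                     meta$phenotype_id))
  sim <- simulate_multiomics(genotypes, meta, effects, noise_sd = 1,
                             covariates = covariates,
                             covariate_loadings = loadings,
                             protein_missing_rate = protein_missing_rate,
                             seed = seed + 2L)
  list(genotypes = genotypes, phenos = sim$phenos, covariates = covariates,
       truth = sim$truth)
}

#' Run the cis pipeline end-to-end on a study
#'
#' Preprocess (impute, rank-normalize, residualize on covariates +
#' phenotype PCs per layer), run the primary cis pass, call significant
#' QTLs and run the stepwise conditional analysis on the significant set.
#' Deterministic given the study and seed.
#'
#' @param study A \code{\link{simulate_study}} result (or same shape).
#' @param n_perm Permutations for the cis pass and conditional scans.
#' @param n_pcs Phenotype PCs used as extra covariates (small default for
#'   desk-scale studies; see \code{\link{default_pc_counts}} for the
#'   full-scale per-layer defaults).
#' @param fdr Primary FDR; \code{cond_fdr} seeds the conditional pass.
#' @param seed Integer seed.
#' @return List: \code{cis} (per-phenotype records), \code{significant},
#'   \code{signals} (conditional SignalList rows), \code{threshold}.
#' @export
run_cis_pipeline <- function(study, n_perm = 200L, n_pcs = 2L, fdr = 0.05,
                             cond_fdr = 0.01, seed = 1L) {
  ph <- study$phenos
  flt <- filter_phenotypes(ph)
  ph <- flt$phenos
  V <- apply(ph$values, 2, mean_impute)
  V <- apply(V, 2, rank_normalize)
  dimnames(V) <- dimnames(ph$values)
  ph <- phenotype_matrix(V, ph$meta)
  covs <- study$covariates
  if (n_pcs > 0)
    covs <- cbind(covs, compute_phenotype_pcs(ph, n_pcs))
  cis <- map_cis(study$genotypes, ph, covs, n_perm = n_perm, seed = seed)
  sig <- call_cis_qtls(cis, fdr = fdr)
  thr_records <- call_cis_qtls(cis, fdr = 1)
  signals <- list()
  seed_set <- thr_records[thr_records$qvalue <= cond_fdr, , drop = FALSE]
  if (nrow(seed_set)) {
    thr <- max(seed_set$p_beta_adjusted)
    for (i in seq_len(nrow(seed_set))) {
      pid <- seed_set$phenotype_id[i]
      j <- match(pid, ph$meta$phenotype_id)
      w <- cis_window(study$genotypes, ph$meta$chrom[j], ph$meta$tss[j])
      signals[[i]] <- conditional_signals(
        study$genotypes, ph$values[, j], covs, w$variant_id, thr,
        n_perm = n_perm, seed = (seed + 7L * i) %% .Machine$integer.max,
        phenotype_id = pid)
    }
  }
  signals <- do.call(rbind, signals)
  list(cis = cis, significant = sig, signals = signals,
       threshold = if (nrow(seed_set)) max(seed_set$p_beta_adjusted) else NA)
}
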
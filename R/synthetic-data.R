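# Synthetic multi-omics study generator.  Genotypes are drawn under
# Hardy-Weinberg equilibrium; LD blocks are built by copying a shared latent
# haplotype with a per-variant flip probability solved from the target
# pairwise r2, which gives closed-form control of within-block LD.

#' Variant specification table
#'
#' Convenience constructor for the variant spec consumed by
#' \code{\link{simulate_genotypes}}.
#'
#' @param variant_id,chrom,pos,maf Per-variant id, chromosome, 1-based
#'   position and minor allele frequency in (0.01, 0.5].
#' @param block_id Integer LD-block label (variants sharing a label and
#'   chromosome are generated in LD); NA for unlinked variants.
#' @param block_r2 Target pairwise dosage r2 within the block, in [0, 1].
#' @return data.frame usable as \code{specs}.
#' @export
variant_specs <- function(variant_id, chrom, pos, maf, block_id = NA,
                          block_r2 = NA) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, maf = maf,
             block_id = block_id, block_r2 = block_r2,
             stringsAsFactors = FALSE)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant's two alleles are drawn independently at its MAF (dosage =
#' alternate-allele count in \{0, 1, 2\}).  Variants sharing a
#' \code{block_id} copy a shared latent haplotype pair with per-allele flip
#' probability \eqn{\epsilon = 1 - r_2^{1/4}}, so that the pairwise dosage
#' correlation squared between any two block members is the block's target
#' \code{block_r2} (exact when members share a MAF, which the bundled study
#' generator guarantees).
#'
#' @param specs Variant spec table, see \code{\link{variant_specs}};
#'   positions must be strictly increasing within chromosome.
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed; identical inputs give identical matrices.
#' @return A \code{\link{genotype_matrix}} with realized \code{maf} added to
#'   the metadata.
#' @export
simulate_genotypes <- function(specs, n_samples, seed = 1L) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  stopifnot(n_samples >= 2)
  if (anyDuplicated(specs$variant_id)) stop("duplicate variant_id")
  if (any(specs$maf <= 0 | specs$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  for (ch in unique(specs$chrom)) {
    ps <- specs$pos[specs$chrom == ch]
    if (any(diff(ps) <= 0)) stop("pos must be strictly increasing within chrom")
  }
  if (is.null(specs$block_id)) specs$block_id <- NA
  if (is.null(specs$block_r2)) specs$block_r2 <- NA
  set.seed(as.integer(seed))
  n <- as.integer(n_samples)
  m <- nrow(specs)
  D <- matrix(0L, n, m)
  bkey <- ifelse(is.na(specs$block_id), paste0("u", seq_len(m)),
                 paste0(specs$chrom, ":", specs$block_id))
  for (grp in split(seq_len(m), bkey)[unique(bkey)]) {
    if (length(grp) == 1L || is.na(specs$block_r2[grp[1]])) {
      for (j in grp)
        D[, j] <- rbinom(n, 1L, specs$maf[j]) + rbinom(n, 1L, specs$maf[j])
    } else {
      r2 <- specs$block_r2[grp[1]]
      eps <- 1 - r2^(1 / 4)
      p0 <- mean(specs$maf[grp])
      h1 <- rbinom(n, 1L, p0)         # latent haplotype pair
      h2 <- rbinom(n, 1L, p0)
      for (j in grp) {
        pj <- specs$maf[j]
        a1 <- ifelse(runif(n) < eps, rbinom(n, 1L, pj), h1)
        a2 <- ifelse(runif(n) < eps, rbinom(n, 1L, pj), h2)
        D[, j] <- a1 + a2
      }
    }
  }
  colnames(D) <- specs$variant_id
  rownames(D) <- sprintf("S%04d", seq_len(n))
  meta <- specs
  meta$realized_maf <- colMeans(D) / 2
  genotype_matrix(D, meta)
}

#' Planted-effect table
#'
#' One row per planted genetic effect.  \code{mode} is one of \code{cis}
#' (direct local effect), \code{trans_direct} (direct distal effect) or
#' \code{trans_mediated} (the effect reaches the phenotype through
#' \code{mediator_id}: the contribution is \code{beta} times the mediator's
#' value, so the marginal SNP slope is the product of the path
#' coefficients).  \code{beta} is in phenotype-SD units per allele
#' (pre-noise) for direct modes, and the mediator-to-target slope for
#' \code{trans_mediated}.
#'
#' @param phenotype_id,variant_id,beta,mode,mediator_id See description.
#' @return data.frame of planted effects.
#' @export
planted_effects <- function(phenotype_id, variant_id, beta, mode = "cis",
                            mediator_id = NA) {
  pe <- data.frame(phenotype_id = phenotype_id, variant_id = variant_id,
                   beta = beta, mode = mode, mediator_id = mediator_id,
                   stringsAsFactors = FALSE)
  bad <- (pe$mode == "trans_mediated") != !is.na(pe$mediator_id)
  if (any(bad)) stop("mediator_id must be present iff mode is trans_mediated")
  if (!all(pe$mode %in% c("cis", "trans_direct", "trans_mediated")))
    stop("unknown effect mode")
  pe
}

#' Simulate multi-layer molecular phenotypes with planted architecture
#'
#' Builds each phenotype as the sum of its planted genetic effects (direct
#' effects use the standardized dosage; mediated effects add \code{beta}
#' times the mediator phenotype), covariate loadings and Gaussian noise,
#' processing phenotypes in topological order of the mediation graph (cycles
#' are an error).  Missingness is injected only into the protein layer,
#' missing completely at random at \code{protein_missing_rate} per protein
#' (capped at 8.5\%).
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param pheno_meta Phenotype metadata data.frame (see
#'   \code{\link{phenotype_matrix}}).
#' @param effects Planted effects, see \code{\link{planted_effects}}.
#' @param noise_sd Per-phenotype noise SD (recycled), > 0 unless exactly 0 to
#'   plant noiseless effects for testing.
#' @param covariates Optional covariate matrix.
#' @param covariate_loadings Optional matrix covariates x phenotypes.
#' @param protein_missing_rate MCAR missingness for proteins, <= 0.085.
#' @param standardize Standardize each phenotype (z-score) after generation.
#' @param seed Integer seed.
#' @return List with \code{phenos} (a \code{PhenotypeMatrix}) and
#'   \code{truth} (effects, noise_sd, covariate_loadings) recording the
#'   planted ground truth.
#' @export
simulate_multiomics <- function(genotypes, pheno_meta, effects,
                                noise_sd = 1, covariates = NULL,
                                covariate_loadings = NULL,
                                protein_missing_rate = 0,
                                standardize = TRUE, seed = 1L) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  pheno_meta <- as.data.frame(pheno_meta, stringsAsFactors = FALSE)
  if (protein_missing_rate > 0.085)
    stop("protein_missing_rate exceeds the 8.5% ceiling")
  pid <- pheno_meta$phenotype_id
  if (!all(effects$phenotype_id %in% pid))
    stop("effect references unknown phenotype")
  if (!all(effects$variant_id %in% genotypes$variants$variant_id))
    stop("effect references unknown variant")
  med <- effects[effects$mode == "trans_mediated", , drop = FALSE]
  if (!all(is.na(med$mediator_id) | med$mediator_id %in% pid))
    stop("mediator references unknown phenotype")
  # topological order over mediation edges mediator -> target
  order_ids <- .topo_order(pid, med)
  set.seed(as.integer(seed))
  n <- nrow(genotypes$dosage)
  noise_sd <- rep(noise_sd, length.out = length(pid))
  names(noise_sd) <- pid
  Gs <- scale(genotypes$dosage)
  Gs[is.nan(Gs)] <- 0
  V <- matrix(NA_real_, n, length(pid),
              dimnames = list(rownames(genotypes$dosage), pid))
  for (id in order_ids) {
    y <- rnorm(n, sd = noise_sd[id])
    ef <- effects[effects$phenotype_id == id, , drop = FALSE]
    for (r in seq_len(nrow(ef))) {
      if (ef$mode[r] == "trans_mediated") {
        y <- y + ef$beta[r] * V[, ef$mediator_id[r]]
      } else {
        y <- y + ef$beta[r] * Gs[, ef$variant_id[r]]
      }
    }
    if (!is.null(covariate_loadings))
      y <- y + as.matrix(covariates) %*% covariate_loadings[, id]
    V[, id] <- y
  }
  if (standardize) {
    V <- scale(V)
    V[is.nan(V)] <- 0
    attr(V, "scaled:center") <- NULL
    attr(V, "scaled:scale") <- NULL
  }
  if (protein_missing_rate > 0) {
    for (j in which(pheno_meta$type == "protein")) {
      drop <- runif(n) < protein_missing_rate
      V[drop, j] <- NA
    }
  }
  truth <- list(effects = effects, noise_sd = noise_sd,
                covariate_loadings = covariate_loadings)
  list(phenos = phenotype_matrix(V, pheno_meta), truth = truth)
}

# Kahn topological sort of phenotypes under mediator -> target edges.
.topo_order <- function(ids, mediated) {
  if (nrow(mediated) == 0L) return(ids)
  deps <- split(mediated$mediator_id, mediated$phenotype_id)
  remaining <- ids
  done <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id) {
      d <- deps[[id]]
      is.null(d) || all(d %in% done)
    }, logical(1))]
    if (!length(ready)) stop("cyclic mediation graph")
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  done
}

#' Plant a single causal trio
#'
#' Generates a (SNP, phenotype 1, phenotype 2) trio under exactly one of the
#' three causal factorizations scored by \code{\link{score_trio_models}}:
#' \code{direction1} (SNP -> P1 -> P2), \code{direction2} (SNP -> P2 -> P1)
#' or \code{independent} (SNP -> P1, SNP -> P2, no phenotype edge).  With
#' \code{two_snp = TRUE} a second SNP in LD \code{ld_r2 > 0.9} with the
#' first drives the second phenotype.
#'
#' @param model One of \code{"direction1"}, \code{"direction2"},
#'   \code{"independent"}.
#' @param n_samples Samples to draw.
#' @param beta_snp SNP-to-phenotype slope on the standardized dosage.
#' @param beta_path Phenotype-to-phenotype path slope (ignored for
#'   \code{independent}).
#' @param noise_sd Gaussian noise SD for both phenotypes.
#' @param two_snp Use an LD pair of SNPs instead of one.
#' @param ld_r2 Target LD of the pair (must exceed 0.9).
#' @param maf Minor allele frequency of the planted SNP(s).
#' @param seed Integer seed.
#' @return List with \code{genotypes}, \code{phenos} (2-column
#'   \code{PhenotypeMatrix}, gene layer, unanchored), \code{truth} (the trio
#'   label and parameters).
#' @export
plant_trio <- function(model = c("direction1", "direction2", "independent"),
                       n_samples, beta_snp, beta_path = 0, noise_sd = 1,
                       two_snp = FALSE, ld_r2 = 0.95, maf = 0.3, seed = 1L) {
  model <- match.arg(model)
  if (two_snp && ld_r2 <= 0.9)
    stop("two-SNP trios require ld_r2 > 0.9")
  specs <- if (two_snp) {
    variant_specs(c("snp1", "snp2"), "1", c(1000L, 2000L), maf,
                  block_id = 1L, block_r2 = ld_r2)
  } else {
    variant_specs("snp1", "1", 1000L, maf)
  }
  geno <- simulate_genotypes(specs, n_samples, seed = seed)
  set.seed(as.integer(seed) + 1L)
  g1 <- as.vector(scale(geno$dosage[, "snp1"]))
  g2 <- if (two_snp) as.vector(scale(geno$dosage[, "snp2"])) else g1
  n <- n_samples
  e1 <- rnorm(n, sd = noise_sd); e2 <- rnorm(n, sd = noise_sd)
  if (model == "direction1") {
    p1 <- beta_snp * g1 + e1
    p2 <- beta_path * p1 + e2
  } else if (model == "direction2") {
    p2 <- beta_snp * g2 + e2
    p1 <- beta_path * p2 + e1
  } else {
    p1 <- beta_snp * g1 + e1
    p2 <- beta_snp * g2 + e2
  }
  meta <- data.frame(phenotype_id = c("P1", "P2"), type = "gene",
                     stringsAsFactors = FALSE)
  pm <- cbind(P1 = p1, P2 = p2)
  rownames(pm) <- rownames(geno$dosage)
  phen <- phenotype_matrix(pm, meta)
  truth <- list(trio_labels = c(trio1 = model),
                beta_snp = beta_snp, beta_path = beta_path,
                noise_sd = noise_sd, two_snp = two_snp, ld_r2 = ld_r2)
  list(genotypes = geno, phenos = phen, truth = truth)
}
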
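# Genome-wide distal (trans) QTL discovery.  Anchored phenotypes exclude all
# variants within 5 Mb of their TSS (and keep other chromosomes); metabolites
# have no anchor and are scanned genome-wide with no exclusion.  Only
# candidate pairs below a storage threshold (1e-4) are retained.

# Logical mask of variants allowed for a phenotype anchor.
.trans_mask <- function(variants, chrom, tss, exclusion_mb) {
  if (is.na(chrom)) return(rep(TRUE, nrow(variants)))
  variants$chrom != chrom | abs(variants$pos - tss) > exclusion_mb * 1e6
}

#' Genome-wide trans-QTL candidate scan
#'
#' Scans every phenotype against all allowed variants and stores pairs with
#' nominal p below \code{store_threshold}.  Phenotypes should be residuals
#' on known technical covariates only (no phenotype PCs, which can absorb
#' genuine trans signal); pass \code{covariates = NULL} in that case.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param phenos A \code{\link{phenotype_matrix}} of residualized phenotypes.
#' @param covariates Optional covariates for the per-variant tests.
#' @param exclusion_mb Exclusion half-width around the TSS in Mb (anchored
#'   phenotypes only).
#' @param store_threshold Keep pairs with p below this.
#' @return data.frame of candidates: \code{phenotype_id}, \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{distance_to_tss} (NA when unanchored or
#'   on another chromosome), \code{beta}, \code{p_nominal}.
#' @export
trans_scan <- function(genotypes, phenos, covariates = NULL,
                       exclusion_mb = 5, store_threshold = 1e-4) {
  stopifnot(inherits(phenos, "PhenotypeMatrix"))
  v <- genotypes$variants
  meta <- phenos$meta
  out <- vector("list", ncol(phenos$values))
  for (j in seq_len(ncol(phenos$values))) {
    mask <- .trans_mask(v, meta$chrom[j], meta$tss[j], exclusion_mb)
    if (!any(mask)) next
    sc <- nominal_scan(genotypes, phenos$values[, j], covariates,
                       v$variant_id[mask])
    hit <- sc[sc$p_nominal < store_threshold, , drop = FALSE]
    if (nrow(hit) == 0L) next
    vi <- match(hit$variant_id, v$variant_id)
    dist <- if (is.na(meta$chrom[j])) NA_real_ else
      ifelse(v$chrom[vi] == meta$chrom[j], abs(v$pos[vi] - meta$tss[j]),
             NA_real_)
    out[[j]] <- data.frame(phenotype_id = meta$phenotype_id[j],
                           variant_id = hit$variant_id,
                           chrom = v$chrom[vi], pos = v$pos[vi],
                           distance_to_tss = dist,
                           beta = hit$beta, p_nominal = hit$p_nominal,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(phenotype_id = character(), variant_id = character(),
                      chrom = character(), pos = integer(),
                      distance_to_tss = numeric(), beta = numeric(),
                      p_nominal = numeric())
  rownames(res) <- NULL
  res
}

#' Remove trans candidates flagged by annotation tables
#'
#' Artifact control for distal scans: drops candidates whose phenotype is in
#' the low-mappability table, whose variant is in the repetitive-region
#' table, or whose (phenotype, variant) pair is in the cross-mappability
#' table.  A missing (NULL) table passes everything through with a warning.
#'
#' @param candidates Output of \code{\link{trans_scan}}.
#' @param low_mappability_phenotypes Character vector of phenotype ids.
#' @param repetitive_variants Character vector of variant ids.
#' @param cross_map_pairs data.frame with \code{phenotype_id},
#'   \code{variant_id}.
#' @return List with the filtered \code{candidates} and a \code{removed}
#'   report.
#' @export
apply_trans_filters <- function(candidates,
                                low_mappability_phenotypes = NULL,
                                repetitive_variants = NULL,
                                cross_map_pairs = NULL) {
  if (is.null(low_mappability_phenotypes) && is.null(repetitive_variants) &&
      is.null(cross_map_pairs))
    warning("no annotation tables supplied: candidates passed through")
  flag <- rep("", nrow(candidates))
  if (!is.null(low_mappability_phenotypes))
    flag[candidates$phenotype_id %in% low_mappability_phenotypes] <-
      "gene_low_mappability"
  if (!is.null(repetitive_variants))
    flag[flag == "" & candidates$variant_id %in% repetitive_variants] <-
      "snp_repetitive"
  if (!is.null(cross_map_pairs)) {
    key <- paste(candidates$phenotype_id, candidates$variant_id)
    bad <- key %in% paste(cross_map_pairs$phenotype_id,
                          cross_map_pairs$variant_id)
    flag[flag == "" & bad] <- "cross_map_pair"
  }
  drop <- flag != ""
  list(candidates = candidates[!drop, , drop = FALSE],
       removed = data.frame(candidates[drop, c("phenotype_id", "variant_id")],
                            reason = flag[drop], stringsAsFactors = FALSE))
}

#' Phenotype-level permutation thresholds for the trans scan
#'
#' For each phenotype, permutes the sample labels and records the
#' genome-wide minimum p over the allowed variants per permutation; the
#' phenotype-level adjusted p is the empirical
#' \eqn{(1 + \#\{perm\ min \le p_{obs}\})/(1 + B)} at the phenotype's
#' observed best p.  Expression phenotypes use 50 permutations by default,
#' proteins and metabolites 100.  Storey q-values across phenotypes control
#' the study-wide FDR.  A beta-fit variant of the phenotype-level p is
#' available with \code{method = "beta"}.
#'
#' @inheritParams trans_scan
#' @param n_perm Named vector of permutation counts by phenotype type
#'   (recycled default \code{c(gene = 50, exon = 50, splice = 50, protein =
#'   100, metabolite = 100)}).
#' @param seed Base seed (per-phenotype seeds derived from it).
#' @param method \code{"empirical"} (default) or \code{"beta"}.
#' @return data.frame per phenotype: \code{phenotype_id}, lead
#'   \code{variant_id}, \code{p_obs}, \code{p_adjusted}, \code{qvalue},
#'   \code{n_perm}.
#' @export
trans_threshold <- function(genotypes, phenos, covariates = NULL,
                            exclusion_mb = 5,
                            n_perm = c(gene = 50L, exon = 50L, splice = 50L,
                                       protein = 100L, metabolite = 100L),
                            seed = 1L, method = c("empirical", "beta")) {
  method <- match.arg(method)
  stopifnot(inherits(phenos, "PhenotypeMatrix"))
  v <- genotypes$variants
  meta <- phenos$meta
  rows <- vector("list", ncol(phenos$values))
  for (j in seq_len(ncol(phenos$values))) {
    mask <- .trans_mask(v, meta$chrom[j], meta$tss[j], exclusion_mb)
    if (!any(mask)) next
    vids <- v$variant_id[mask]
    sc <- nominal_scan(genotypes, phenos$values[, j], covariates, vids)
    sc <- sc[order(sc$p_nominal), , drop = FALSE]
    B <- n_perm[[meta$type[j]]]
    minp <- suppressWarnings(
      permutation_minp(genotypes, phenos$values[, j], covariates, vids,
                       n_perm = B,
                       seed = (as.integer(seed) + j) %% .Machine$integer.max))
    p_obs <- sc$p_nominal[1]
    p_adj <- if (method == "empirical") {
      (1 + sum(minp <= p_obs)) / (1 + B)
    } else {
      fit <- fit_beta_approx(minp)
      adjusted_pvalue(p_obs, fit)
    }
    rows[[j]] <- data.frame(phenotype_id = meta$phenotype_id[j],
                            variant_id = sc$variant_id[1], p_obs = p_obs,
                            p_adjusted = p_adj, n_perm = B,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable phenotypes")
  out$qvalue <- storey_qvalue(out$p_adjusted)$qvalues
  rownames(out) <- NULL
  out
}

#' Merge windows around significant trans signals into regions
#'
#' Half-open \code{+/- window} intervals around each significant trans
#' variant are merged by a leftmost-sorted sweep into non-overlapping
#' regions per chromosome.
#'
#' @param variants data.frame with \code{chrom}, \code{pos} of significant
#'   trans variants.
#' @param window Half-width in bp.
#' @return data.frame of regions: \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @export
merge_trans_regions <- function(variants, window = 1e6) {
  iv <- data.frame(chrom = as.character(variants$chrom),
                   start = pmax(1, variants$pos - window),
                   end = variants$pos + window)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- list()
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    s <- x$start[1]; e <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] < e) e <- max(e, x$end[i])   # half-open: touching splits
      else { out[[length(out) + 1L]] <- c(ch, s, e); s <- x$start[i]; e <- x$end[i] }
    }
    out[[length(out) + 1L]] <- c(ch, s, e)
  }
  reg <- data.frame(chrom = vapply(out, `[`, "", 1),
                    start = as.numeric(vapply(out, `[`, "", 2)),
                    end = as.numeric(vapply(out, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  reg$region_id <- sprintf("region%03d", seq_len(nrow(reg)))
  reg[, c("region_id", "chrom", "start", "end")]
}

#' Region-based secondary trans signals
#'
#' Merges \code{+/- 1 Mb} windows around the significant trans variants into
#' non-overlapping regions and runs the forward-backward stepwise scan
#' within each region for each affected phenotype, reusing the conditional
#' machinery of the cis stage.
#'
#' @param sig_trans data.frame of significant trans associations with
#'   \code{phenotype_id}, \code{variant_id}, \code{chrom}, \code{pos}.
#' @inheritParams conditional_signals
#' @param phenos The residualized \code{\link{phenotype_matrix}}.
#' @param window Region half-width in bp.
#' @return data.frame of signals with \code{region_id} and \code{rank}.
#' @export
secondary_trans <- function(sig_trans, genotypes, phenos, covariates = NULL,
                            threshold, window = 1e6, n_perm = 200L,
                            seed = 1L) {
  stopifnot(nrow(sig_trans) > 0)
  regions <- merge_trans_regions(sig_trans[, c("chrom", "pos")], window)
  v <- genotypes$variants
  out <- list()
  for (r in seq_len(nrow(regions))) {
    vids <- v$variant_id[v$chrom == regions$chrom[r] &
                           v$pos >= regions$start[r] &
                           v$pos < regions$end[r]]
    if (!length(vids)) next
    in_region <- sig_trans$chrom == regions$chrom[r] &
      sig_trans$pos >= regions$start[r] & sig_trans$pos < regions$end[r]
    for (pid in unique(sig_trans$phenotype_id[in_region])) {
      y <- phenos$values[, pid]
      sig <- conditional_signals(genotypes, y, covariates, vids, threshold,
                                 n_perm = n_perm,
                                 seed = (as.integer(seed) + r) %% .Machine$integer.max,
                                 phenotype_id = pid)
      if (nrow(sig)) {
        sig$region_id <- regions$region_id[r]
        out[[length(out) + 1L]] <- sig
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  attr(res, "regions") <- regions
  res
}
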
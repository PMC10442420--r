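# Sharing and enrichment statistics: pi1 estimation of shared genetic
# regulation across phenotype layers / tissues, per-SNP p-value combination,
# Fisher enrichments, power-matched enrichment, pleiotropy pair statistics
# and interval (e.g. TAD) membership.

#' Estimate the shared proportion of associations (pi1)
#'
#' Given the p-values, in a target set, of associations discovered in
#' another set (tissue, phenotype layer or study), estimates the proportion
#' drawn from the alternative hypothesis as \eqn{\pi_1 = 1 - \hat\pi_0}
#' using the Storey machinery, with a percentile bootstrap confidence
#' interval from resampling the p-values.
#'
#' @param p_target P-values of the discovery-significant pairs in the target
#'   set (>= 50 recommended; small sets give very wide intervals).
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Interval coverage.
#' @param seed Integer seed for the bootstrap.
#' @return List (\code{Pi1Estimate}): \code{pi1}, \code{pi0},
#'   \code{n_pvalues}, \code{ci_low}, \code{ci_high}.
#' @export
pi1_sharing <- function(p_target, n_boot = 100L, conf = 0.95, seed = 1L) {
  if (length(p_target) == 0L) stop("empty p-value vector")
  qv <- storey_qvalue(p_target)
  set.seed(as.integer(seed))
  m <- length(p_target)
  boot <- vapply(seq_len(n_boot), function(i)
    storey_qvalue(sample(p_target, m, replace = TRUE))$pi1, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
  list(pi1 = qv$pi1, pi0 = qv$pi0, n_pvalues = m,
       ci_low = max(0, ci[1]), ci_high = min(1, ci[2]))
}

#' Combine the p-values of one SNP across target phenotypes
#'
#' \code{method = "product"} returns the raw product of the p-values (used
#' to summarize a SNP's joint evidence across phenotypes; note the product
#' is not itself a calibrated p-value).  \code{method = "fisher"} returns
#' Fisher's combined probability, the \eqn{\chi^2_{2m}} upper tail of
#' \eqn{-2\sum \ln p}, which is calibrated under independence and is the
#' recommended alternative.
#'
#' @param p P-values in (0, 1]; exact zeros are clamped to the smallest
#'   positive double.
#' @param method \code{"product"} or \code{"fisher"}.
#' @return Scalar combined value.
#' @export
combine_snp_pvalues <- function(p, method = c("product", "fisher")) {
  method <- match.arg(method)
  stopifnot(length(p) >= 1, all(p <= 1))
  p <- pmax(p, .Machine$double.xmin)
  if (method == "product") return(prod(p))
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Fisher exact enrichment on a 2x2 table
#'
#' Sample odds ratio \eqn{(a d)/(b c)} (with Haldane's 0.5 correction iff
#' any cell is zero) and the exact two-sided Fisher p-value.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List (\code{EnrichmentResult}): \code{table}, \code{odds_ratio},
#'   \code{p_value}.
#' @export
fisher_enrichment <- function(table) {
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (all(tab == 0)) stop("all-zero table")
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p)
}

#' Power-matched GWAS enrichment
#'
#' When comparing GWAS-overlap enrichment between QTL sets of very different
#' sizes (e.g. eSNPs vs pSNPs), takes only the top \code{match_to} SNPs of
#' the larger set ranked by significance (best nominal p per SNP) and
#' recomputes the enrichment, so both sets carry comparable power.  Ties at
#' the selection boundary are broken randomly per draw; with no ties a
#' single draw is deterministic.
#'
#' @param p_large Best nominal p per SNP of the larger set.
#' @param flag_large Logical GWAS flag per SNP of the larger set.
#' @param flag_small Logical GWAS flag per SNP of the smaller set.
#' @param match_to Number of top SNPs to keep (default: size of the smaller
#'   set; may not exceed the larger set's size).
#' @param n_draws Random draws over boundary ties.
#' @param seed Integer seed.
#' @return List: \code{draws} (per-draw \code{\link{fisher_enrichment}}
#'   results), \code{odds_ratio} (median across draws), \code{p_value}
#'   (median across draws).
#' @export
matched_subsample_enrichment <- function(p_large, flag_large, flag_small,
                                         match_to = length(flag_small),
                                         n_draws = 1L, seed = 1L) {
  stopifnot(length(p_large) == length(flag_large))
  if (match_to > length(p_large))
    stop("match_to exceeds the larger set's size")
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n_draws), function(d) {
    o <- order(p_large, runif(length(p_large)))
    sel <- flag_large[o[seq_len(match_to)]]
    tab <- rbind(large = c(sum(sel), sum(!sel)),
                 small = c(sum(flag_small), sum(!flag_small)))
    colnames(tab) <- c("gwas", "not_gwas")
    fisher_enrichment(tab)
  })
  list(draws = draws,
       odds_ratio = stats::median(vapply(draws, `[[`, 0, "odds_ratio")),
       p_value = stats::median(vapply(draws, `[[`, 0, "p_value")))
}

#' Pleiotropy pair statistics
#'
#' For pairs of phenotypes sharing a lead variant: a two-sided Wilcoxon
#' rank-sum test of the TSS distance between sign-concordant and
#' sign-discordant pairs, and a Fisher enrichment of strand sharing by sign
#' concordance.
#'
#' @param pairs data.frame with \code{tss_distance} (bp),
#'   \code{sign_concordant} (logical), \code{same_strand} (logical).
#' @return List: \code{wilcoxon_distance} (list with \code{statistic},
#'   \code{p_value}), \code{strand_or} (\code{\link{fisher_enrichment}}
#'   result, or NULL when strand data is absent).
#' @export
pleiotropy_pair_stats <- function(pairs) {
  stopifnot(all(c("tss_distance", "sign_concordant") %in% names(pairs)))
  conc <- pairs$sign_concordant
  if (length(unique(conc)) < 2L)
    stop("need both sign-concordant and discordant pairs")
  if (min(table(conc)) < 2L)
    stop("need >= 2 pairs in each concordance class")
  wt <- wilcox.test(pairs$tss_distance[!conc], pairs$tss_distance[conc],
                    exact = FALSE)
  strand_or <- NULL
  if (!is.null(pairs$same_strand)) {
    tab <- table(factor(!pairs$same_strand, c(FALSE, TRUE)),
                 factor(!conc, c(FALSE, TRUE)))
    strand_or <- fisher_enrichment(unclass(tab))
  }
  list(wilcoxon_distance = list(statistic = unname(wt$statistic),
                                p_value = wt$p.value),
       strand_or = strand_or)
}

#' Assign genomic positions to intervals
#'
#' Labels each (chrom, pos) with the id of the covering interval, if any.
#' Intervals follow BED conventions: half-open, 0-based \code{[start, end)},
#' assumed sorted within chromosome; when several intervals cover a
#' position the first (leftmost) wins.
#'
#' @param positions data.frame with \code{chrom}, \code{pos}.
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{id}.
#' @return Character vector of interval ids (NA when uncovered), one per
#'   position.
#' @export
assign_intervals <- function(positions, intervals) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)),
            all(c("chrom", "start", "end", "id") %in% names(intervals)))
  if (any(intervals$end < intervals$start)) stop("malformed intervals")
  out <- rep(NA_character_, nrow(positions))
  for (ch in unique(positions$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!nrow(iv)) next
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    pidx <- which(positions$chrom == ch)
    for (i in pidx) {
      pos <- positions$pos[i]
      hit <- which(iv$start <= pos & pos < iv$end)
      if (length(hit)) out[i] <- iv$id[hit[1]]
    }
  }
  out
}
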
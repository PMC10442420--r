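# Approximate-Bayes-factor colocalization under the single-causal-variant
# assumption, with the renormalized sharing ratio P(H4') = PP4/(PP3 + PP4).
# All hypothesis sums are taken in log space (log-sum-exp), so large |z|
# never overflow.

#' Wakefield log approximate Bayes factor
#'
#' \eqn{\log ABF = \tfrac12 \log(1 - r) + z^2 r / 2} with \eqn{z =
#' \beta/se} and shrinkage \eqn{r = W^2/(W^2 + se^2)}; \eqn{W} is the prior
#' SD of the effect under the alternative (0.15 for quantitative traits).
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior effect SD.
#' @return log ABF (vectorized).
#' @export
wakefield_abf <- function(beta, se, W = 0.15) {
  stopifnot(all(se > 0))
  z <- beta / se
  r <- W^2 / (W^2 + se^2)
  0.5 * log1p(-r) + z^2 * r / 2
}

# Reconstruct se for a quantitative trait from p, maf, n (unit-variance
# trait approximation var(beta) = 1/(2 n f (1-f))); beta recovered as z*se.
.se_from_pmafn <- function(p, maf, n) {
  sqrt(1 / (2 * n * maf * (1 - maf)))
}

#' Prepare per-SNP log-ABFs from summary statistics
#'
#' Accepts either \code{beta} + \code{se}, or \code{p} + \code{maf} +
#' \code{n} (the standard quantitative-trait fallback: \code{se} is
#' reconstructed from allele frequency and sample size and \code{|beta| =
#' |z| se}).  When per-SNP \code{n} varies, the median is used.
#'
#' @param summary data.frame with \code{variant_id} and either
#'   \code{beta}, \code{se} or \code{p}, \code{maf}, \code{n}.
#' @param W Prior effect SD.
#' @return data.frame \code{variant_id}, \code{labf}.
#' @export
abf_from_summary <- function(summary, W = 0.15) {
  if (all(c("beta", "se") %in% names(summary))) {
    labf <- wakefield_abf(summary$beta, summary$se, W)
  } else if (all(c("p", "maf", "n") %in% names(summary))) {
    n <- stats::median(summary$n)
    se <- .se_from_pmafn(summary$p, summary$maf, n)
    z <- qnorm(pmax(summary$p, 1e-300) / 2, lower.tail = FALSE)
    labf <- wakefield_abf(z * se, se, W)
  } else stop("need beta+se or p+maf+n columns")
  data.frame(variant_id = summary$variant_id, labf = labf,
             stringsAsFactors = FALSE)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b.
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Colocalization posterior probabilities
#'
#' Single-causal-variant colocalization of two traits over a shared SNP set:
#' sums the per-configuration Bayes factors (in log space) for the five
#' hypotheses — H0 no association, H1/H2 one trait associated, H3 both but
#' with distinct causal variants, H4 both sharing one causal variant — with
#' per-configuration priors \code{p1}, \code{p2}, \code{p12}, and
#' normalizes.
#'
#' @param abf1,abf2 log-ABF vectors for the two traits over the same SNPs
#'   (same order, >= 1 SNP).
#' @param p1,p2 Prior probability a SNP is causal for trait 1 / trait 2
#'   only.
#' @param p12 Prior probability a SNP is causal for both.
#' @return Object of class \code{ColocResult}: \code{pp} (named PP0..PP4,
#'   summing to 1), \code{h4_prime}, \code{priors}, \code{n_snps}.
#' @export
coloc_posteriors <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(length(abf1) == length(abf2), length(abf1) >= 1)
  l1 <- .logsumexp(abf1)
  l2 <- .logsumexp(abf2)
  l12 <- .logsumexp(abf1 + abf2)
  lh0 <- 0
  lh1 <- log(p1) + l1
  lh2 <- log(p2) + l2
  # sum over i != j of exp(abf1_i + abf2_j) = (sum_i)(sum_j) - sum_i(both)
  lh3 <- log(p1) + log(p2) + .logdiffexp(l1 + l2, l12)
  lh4 <- log(p12) + l12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - .logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp,
                 h4_prime = if (pp["PP3"] + pp["PP4"] > 0)
                   unname(pp["PP4"] / (pp["PP3"] + pp["PP4"]))
                 else NA_real_,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_snps = length(abf1)),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNPs:\n", x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("P(H4') = PP4/(PP3+PP4) = %.4f\n", x$h4_prime))
  invisible(x)
}

#' Renormalized sharing probability P(H4')
#'
#' \eqn{PP4 / (PP3 + PP4)}: the probability that the two signals share a
#' causal variant, given that both regions are associated — appropriate
#' when the QTL lead was pre-selected as associated with the GWAS trait.
#'
#' @param result A \code{\link{coloc_posteriors}} result.
#' @return Scalar in [0, 1]; NA (with a warning) when PP3 = PP4 = 0.
#' @export
h4_prime <- function(result) {
  stopifnot(inherits(result, "ColocResult"))
  denom <- result$pp["PP3"] + result$pp["PP4"]
  if (denom == 0) {
    warning("PP3 + PP4 = 0: H4' undefined")
    return(NA_real_)
  }
  unname(result$pp["PP4"] / denom)
}

#' Filter a region's summary statistics for colocalization
#'
#' Keeps variants with \code{p < p_max} anywhere in the region, plus all
#' variants within \code{window_bp} of the lead variant regardless of p.
#'
#' @param summary data.frame with \code{variant_id}, \code{pos}, \code{p}.
#' @param lead_snp Lead variant id (must be present).
#' @param window_bp Window half-width around the lead.
#' @param p_max Region-wide p-value cutoff.
#' @return The filtered summary; error if nothing survives.
#' @export
region_filter <- function(summary, lead_snp, window_bp = 20000, p_max = 0.1) {
  stopifnot(all(c("variant_id", "pos", "p") %in% names(summary)))
  i <- match(lead_snp, summary$variant_id)
  if (is.na(i)) stop("lead variant absent from the region")
  keep <- summary$p < p_max |
    abs(summary$pos - summary$pos[i]) <= window_bp
  if (!any(keep)) stop("no variant passes the region filter")
  summary[keep, , drop = FALSE]
}
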
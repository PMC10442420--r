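# Gaussian Bayesian-network scoring of SNP-phenotype-phenotype trios.
# Each candidate factorization is a product of (i) Gaussian linear
# conditionals (child ~ parents, MLE variance) and (ii) a multinomial
# marginal over observed genotype classes; models are compared by
# score = logL - (k/2) ln n and a trio is conclusive when the best model
# beats both others by a margin of at least delta (default 10).

#' Squared dosage correlation between two variants
#'
#' @param dosage1,dosage2 Dosage vectors (complete cases used).
#' @return r2 in [0, 1].
#' @export
ld_r2 <- function(dosage1, dosage2) {
  ok <- !is.na(dosage1) & !is.na(dosage2)
  d1 <- dosage1[ok]; d2 <- dosage2[ok]
  if (var(d1) == 0 || var(d2) == 0) stop("monomorphic dosage vector")
  cor(d1, d2)^2
}

#' Pseudo-phenotype isolating a single QTL signal
#'
#' Residualizes the phenotype on the covariates and on all of its signal
#' variants except the one under study, so the trio analysis sees exactly
#' one genetic signal.  Collinear conditioning variants are dropped with a
#' warning rather than failing.
#'
#' @param phenotype Numeric vector.
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param all_signal_snps All variant ids with an independent signal on this
#'   phenotype.
#' @param keep_snp The signal to preserve (must be in
#'   \code{all_signal_snps}).
#' @param covariates Optional covariate matrix.
#' @return Residual vector; the association with \code{keep_snp} is
#'   preserved.
#' @export
single_signal_residual <- function(phenotype, genotypes, all_signal_snps,
                                   keep_snp, covariates = NULL) {
  if (!keep_snp %in% all_signal_snps)
    stop("keep_snp is not among the phenotype's signal variants")
  others <- setdiff(all_signal_snps, keep_snp)
  covs <- covariates
  if (length(others)) {
    acc <- genotypes$dosage[, others, drop = FALSE]
    covs <- if (is.null(covs)) acc else cbind(covs, acc)
    d0 <- .design(nrow(acc), covs, allow_drop = TRUE)
    if (ncol(d0$X) < length(others) + 1 +
        (if (is.null(covariates)) 0 else ncol(as.matrix(covariates))))
      warning("collinear conditioning variants dropped")
    covs <- d0$X[, -1, drop = FALSE]
  }
  as.vector(.proj_resid(phenotype, covs))
}

# logL and parameter count of a Gaussian linear conditional child ~ parents.
.gauss_factor <- function(child, parents = NULL) {
  n <- length(child)
  X <- if (is.null(parents)) matrix(1, n, 1) else cbind(1, parents)
  fit <- lm.fit(X, child)
  s2 <- sum(fit$residuals^2) / n
  list(ll = -n / 2 * (log(2 * pi * s2) + 1), k = ncol(X) + 1L)
}

# logL and parameter count of the genotype-class multinomial marginal.
.snp_factor <- function(g) {
  tab <- table(g)
  if (length(tab) < 2L) stop("degenerate genotype: single class observed")
  n <- sum(tab)
  list(ll = sum(tab * log(tab / n)), k = length(tab) - 1L)
}

#' Score the three causal factorizations of a trio
#'
#' Computes, on complete cases, the log-likelihood, parameter count and
#' penalized score \eqn{logL - (k/2)\ln n} of the three causal models for a
#' SNP associated with two (pseudo-)phenotypes:
#' \describe{
#'   \item{direction1}{P(P2 | P1) P(P1 | SNP) P(SNP): the SNP effect on P2
#'     is mediated by P1.}
#'   \item{direction2}{P(P1 | P2) P(P2 | SNP) P(SNP): mediation through P2.}
#'   \item{independent}{P(P1 | SNP) P(P2 | SNP) P(SNP): no phenotype edge.}
#' }
#' With a second variant (an LD pair, one lead per phenotype) the two-SNP
#' factorizations are used: direction1 conditions P1 on SNP1 only,
#' direction2 conditions P2 on SNP2 only, and the independent model uses
#' both marginals.  The best model is the score argmax; the call is
#' conclusive when its margin over the runner-up reaches \code{delta}.
#' Relabeling the phenotypes swaps the two direction scores exactly and
#' leaves the independent score unchanged.
#'
#' @param snp1 Dosage vector of the (first) variant.
#' @param p1,p2 The two pseudo-phenotypes.
#' @param snp2 Optional dosage vector of the LD-paired second variant.
#' @param delta Conclusiveness margin on the score scale.
#' @param include_snp_marginals Include the P(SNP) multinomial factor(s), as
#'   the factorizations dictate; \code{FALSE} scores conditionally on the
#'   genotypes (relevant for two-SNP trios, whose factorizations otherwise
#'   span slightly different variable sets).
#' @return Object of class \code{TrioModelFit}: lists \code{loglik},
#'   \code{k}, \code{score} keyed by model, plus \code{best_model},
#'   \code{margin}, \code{conclusive}, \code{n}, \code{delta}.
#' @export
score_trio_models <- function(snp1, p1, p2, snp2 = NULL, delta = 10,
                              include_snp_marginals = TRUE) {
  ok <- !is.na(snp1) & !is.na(p1) & !is.na(p2)
  if (!is.null(snp2)) ok <- ok & !is.na(snp2)
  snp1 <- snp1[ok]; p1 <- p1[ok]; p2 <- p2[ok]
  if (!is.null(snp2)) snp2 <- snp2[ok]
  n <- length(p1)
  if (n < 100L) stop("need at least 100 complete-case samples")
  two <- !is.null(snp2)
  s1 <- if (include_snp_marginals) .snp_factor(snp1) else list(ll = 0, k = 0L)
  s2 <- if (two && include_snp_marginals) .snp_factor(snp2)
        else list(ll = 0, k = 0L)
  if (!two) snp2 <- snp1
  f_p1_s1 <- .gauss_factor(p1, snp1)
  f_p2_s2 <- .gauss_factor(p2, snp2)
  f_p2_p1 <- .gauss_factor(p2, p1)
  f_p1_p2 <- .gauss_factor(p1, p2)
  models <- list(
    direction1 = list(ll = f_p2_p1$ll + f_p1_s1$ll + s1$ll,
                      k = f_p2_p1$k + f_p1_s1$k + s1$k),
    direction2 = list(ll = f_p1_p2$ll + f_p2_s2$ll +
                        (if (two) s2$ll else s1$ll),
                      k = f_p1_p2$k + f_p2_s2$k + (if (two) s2$k else s1$k)),
    independent = list(ll = f_p1_s1$ll + f_p2_s2$ll + s1$ll +
                         (if (two) s2$ll else 0),
                       k = f_p1_s1$k + f_p2_s2$k + s1$k +
                         (if (two) s2$k else 0L)))
  ll <- vapply(models, `[[`, 0, "ll")
  k <- vapply(models, `[[`, 0L, "k")
  score <- ll - (k / 2) * log(n)
  o <- order(score, decreasing = TRUE)
  margin <- score[o[1]] - score[o[2]]
  structure(list(loglik = ll, k = k, score = score,
                 best_model = names(score)[o[1]], margin = unname(margin),
                 conclusive = unname(margin) >= delta, n = n, delta = delta),
            class = "TrioModelFit")
}

#' @export
print.TrioModelFit <- function(x, ...) {
  cat(sprintf("Trio model fit (n = %d): best = %s, margin = %.2f (%s)\n",
              x$n, x$best_model, x$margin,
              if (x$conclusive) "conclusive" else "inconclusive"))
  print(data.frame(loglik = x$loglik, k = x$k, score = x$score))
  invisible(x)
}

#' Enumerate candidate trios from significant QTL tables
#'
#' Every variant significantly associated with two or more phenotypes forms
#' one trio per phenotype pair; additionally, pairs of lead variants in high
#' LD (\code{r2 > ld_min}) that each lead a different phenotype form two-SNP
#' trios.  Pairs of expression phenotypes listed in \code{exclusion_pairs}
#' (e.g. genes with overlapping exons, whose quantifications are correlated
#' by construction) are excluded.  Each trio is tagged with its QTL context
#' (e.g. \code{cis-e/cis-p}).
#'
#' @param qtl_table data.frame of significant associations with columns
#'   \code{phenotype_id}, \code{variant_id}, \code{phenotype_type} (gene /
#'   exon / splice / protein / metabolite) and \code{context} (\code{cis} or
#'   \code{trans}).
#' @param genotypes Optional \code{\link{genotype_matrix}} for LD-pair
#'   construction; NULL disables two-SNP trios.
#' @param ld_min LD r2 threshold for pairing lead variants.
#' @param exclusion_pairs Optional data.frame with \code{phenotype_a},
#'   \code{phenotype_b} of phenotype pairs to drop (order-insensitive).
#' @return data.frame of trios: \code{trio_id}, \code{snp1}, \code{snp2}
#'   (NA for single-SNP trios), \code{ld_r2}, \code{phen1}, \code{phen2},
#'   \code{qtl_context}.
#' @export
build_trios <- function(qtl_table, genotypes = NULL, ld_min = 0.9,
                        exclusion_pairs = NULL) {
  req <- c("phenotype_id", "variant_id", "phenotype_type", "context")
  stopifnot(all(req %in% names(qtl_table)))
  lab <- function(type, context) {
    code <- c(gene = "e", exon = "e", splice = "s", protein = "p",
              metabolite = "metabo")[type]
    paste0(context, "-", code)
  }
  qtl_table$tag <- lab(qtl_table$phenotype_type, qtl_table$context)
  excluded <- function(a, b) {
    if (is.null(exclusion_pairs)) return(FALSE)
    key <- paste(pmin(a, b), pmax(a, b))
    key %in% paste(pmin(exclusion_pairs$phenotype_a,
                        exclusion_pairs$phenotype_b),
                   pmax(exclusion_pairs$phenotype_a,
                        exclusion_pairs$phenotype_b))
  }
  rows <- list()
  # single-SNP trios: one variant, >= 2 phenotypes
  for (vid in unique(qtl_table$variant_id)) {
    sub <- qtl_table[qtl_table$variant_id == vid, , drop = FALSE]
    sub <- sub[!duplicated(sub$phenotype_id), , drop = FALSE]
    if (nrow(sub) < 2L) next
    cmb <- utils::combn(nrow(sub), 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      if (excluded(sub$phenotype_id[i], sub$phenotype_id[j])) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp1 = vid, snp2 = NA_character_, ld_r2 = NA_real_,
        phen1 = sub$phenotype_id[i], phen2 = sub$phenotype_id[j],
        qtl_context = paste(sub$tag[i], sub$tag[j], sep = "/"),
        stringsAsFactors = FALSE)
    }
  }
  # two-SNP trios: distinct lead variants in high LD, different phenotypes
  if (!is.null(genotypes)) {
    leads <- qtl_table[!duplicated(paste(qtl_table$phenotype_id,
                                         qtl_table$variant_id)), ,
                       drop = FALSE]
    vids <- unique(leads$variant_id)
    if (length(vids) >= 2L) {
      cmb <- utils::combn(length(vids), 2)
      for (c_i in seq_len(ncol(cmb))) {
        va <- vids[cmb[1, c_i]]; vb <- vids[cmb[2, c_i]]
        r2 <- tryCatch(ld_r2(genotypes$dosage[, va], genotypes$dosage[, vb]),
                       error = function(e) NA_real_)
        if (is.na(r2) || r2 <= ld_min) next
        pa <- leads[leads$variant_id == va, , drop = FALSE]
        pb <- leads[leads$variant_id == vb, , drop = FALSE]
        for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
          if (pa$phenotype_id[i] == pb$phenotype_id[j]) next
          if (excluded(pa$phenotype_id[i], pb$phenotype_id[j])) next
          rows[[length(rows) + 1L]] <- data.frame(
            snp1 = va, snp2 = vb, ld_r2 = r2,
            phen1 = pa$phenotype_id[i], phen2 = pb$phenotype_id[j],
            qtl_context = paste(pa$tag[i], pb$tag[j], sep = "/"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp1 = character(), snp2 = character(),
                      ld_r2 = numeric(), phen1 = character(),
                      phen2 = character(), qtl_context = character())
  out <- cbind(trio_id = sprintf("trio%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
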
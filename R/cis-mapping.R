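#' Cis window around a phenotype's TSS
#'
#' Variants within \code{tss +/- window} basepairs on the phenotype's
#' chromosome (1 Mb each side by default), clipped at position 1.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param chrom Chromosome of the phenotype anchor.
#' @param tss Transcription start site (1-based bp).
#' @param window Half-width in bp.
#' @return List with \code{chrom}, \code{start}, \code{end} and
#'   \code{variant_id}, the ids of variants inside the window.
#' @export
cis_window <- function(genotypes, chrom, tss, window = 1e6) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"), !is.na(chrom), !is.na(tss))
  v <- genotypes$variants
  start <- max(1, tss - window)
  end <- tss + window
  sel <- v$chrom == chrom & v$pos >= start & v$pos <= end
  list(chrom = chrom, start = start, end = end,
       variant_id = v$variant_id[sel])
}

#' Fit a beta distribution to permutation minimum p-values
#'
#' Maximum-likelihood Beta(a, b) fit to the per-permutation minimum
#' p-values of a window, initialized by method of moments.  This is the
#' phenotype-level multiple-testing correction: the fitted null distribution
#' of the window's best p-value.  Values at exactly 0 or 1 are clamped to
#' \code{[1/(2B), 1 - 1/(2B)]}.  \code{fit_ok} is \code{FALSE} when the
#' optimizer fails or the Kolmogorov-Smirnov distance between the minima and
#' the fitted beta exceeds 0.2.
#'
#' @param minp Numeric vector of permutation minimum p-values (length >= 50).
#' @return Object of class \code{BetaApproxFit}: list with \code{a}, \code{b},
#'   \code{n_perm}, \code{loglik}, \code{fit_ok}, \code{minp} (the clamped
#'   input, kept for the empirical fallback).
#' @export
fit_beta_approx <- function(minp) {
  B <- length(minp)
  if (B < 50L) stop("need at least 50 permutation minima")
  x <- pmin(pmax(minp, 1 / (2 * B)), 1 - 1 / (2 * B))
  fail <- function() structure(list(a = NA_real_, b = NA_real_, n_perm = B,
                                    loglik = NA_real_, fit_ok = FALSE,
                                    minp = x), class = "BetaApproxFit")
  if (var(x) < .Machine$double.eps) return(fail())
  m <- mean(x); v <- var(x)
  c0 <- max(m * (1 - m) / v - 1, 1e-3)
  init <- log(pmax(c(m * c0, (1 - m) * c0), 1e-3))
  slx <- sum(log(x)); sl1x <- sum(log1p(-x))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -( (a - 1) * slx + (b - 1) * sl1x - B * lbeta(a, b) )
  }
  gr <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    dab <- digamma(a + b)
    -c(a * (slx + B * (dab - digamma(a))),
       b * (sl1x + B * (dab - digamma(b))))
  }
  fit <- try(optim(init, nll, gr, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) return(fail())
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  ks <- suppressWarnings(ks.test(x, pbeta, a, b)$statistic)
  structure(list(a = a, b = b, n_perm = B, loglik = -fit$value,
                 fit_ok = is.finite(a) && is.finite(b) && ks <= 0.2,
                 minp = x),
            class = "BetaApproxFit")
}

#' Beta-approximation adjusted p-value
#'
#' Phenotype-level adjusted p-value \eqn{I_p(a, b)} (the regularized
#' incomplete beta function, i.e. the fitted beta CDF at the nominal p),
#' monotone in the nominal p.  When the fit failed, falls back to the
#' empirical permutation p-value \eqn{(1 + \#\{minp \le p\})/(1 + B)}.
#'
#' @param p_nominal Nominal p-value(s) of the window's best association.
#' @param fit A \code{\link{fit_beta_approx}} result.
#' @return Adjusted p-value(s) in [0, 1].
#' @export
adjusted_pvalue <- function(p_nominal, fit) {
  stopifnot(inherits(fit, "BetaApproxFit"))
  if (isTRUE(fit$fit_ok))
    return(pbeta(p_nominal, fit$a, fit$b))
  vapply(p_nominal,
         function(p) (1 + sum(fit$minp <= p)) / (1 + fit$n_perm),
         numeric(1))
}

#' Storey q-values and pi0 estimation
#'
#' Storey's procedure: \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1 -
#' \lambda))} over a lambda grid, smoothed by a cubic spline and evaluated at
#' the largest lambda, then clamped to [0.001, 1]; q-values are the step-up
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j} on the sorted
#' p-values.  For fewer than 100 p-values the spline is unreliable and a
#' fixed \eqn{\lambda = 0.5} is used instead.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param lambda_grid Lambda grid for the pi0 estimate.
#' @return Object of class \code{QvalueResult}: list with \code{pi0},
#'   \code{pi1}, \code{lambda_grid}, \code{qvalues} (input order).
#' @export
storey_qvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) stop("empty p-value vector")
  if (m < 100L) lambda_grid <- 0.5
  if (length(lambda_grid) == 1L) {
    pi0 <- sum(p > lambda_grid) / (m * (1 - lambda_grid))
  } else {
    pi0_l <- vapply(lambda_grid,
                    function(l) sum(p > l) / (m * (1 - l)), numeric(1))
    sp <- smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- predict(sp, x = max(lambda_grid))$y
  }
  pi0 <- min(max(pi0, 0.001), 1)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  qvalues <- numeric(m)
  qvalues[o] <- q
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda_grid = lambda_grid,
                 qvalues = qvalues),
            class = "QvalueResult")
}

#' Call significant cis-QTLs at a genome-wide FDR
#'
#' Takes one beta-adjusted p-value per phenotype (the window's best SNP; for
#' grouped phenotypes, the best phenotype-SNP pair of the group), computes
#' Storey q-values across phenotypes and returns the records passing the FDR
#' cutoff (default 5\%; the seed set for conditional analysis uses 1\%).
#'
#' @param records data.frame with one row per phenotype, containing at least
#'   \code{phenotype_id}, \code{variant_id} and \code{p_beta_adjusted}.
#' @param fdr FDR threshold on the q-values.
#' @return The significant subset of \code{records}, with a \code{qvalue}
#'   column appended, ordered by q-value.  The full q-value fit is attached
#'   as attribute \code{"qvalue_fit"}.
#' @export
call_cis_qtls <- function(records, fdr = 0.05) {
  stopifnot(all(c("phenotype_id", "variant_id", "p_beta_adjusted")
                %in% names(records)))
  qv <- storey_qvalue(records$p_beta_adjusted)
  records$qvalue <- qv$qvalues
  sig <- records[records$qvalue <= fdr, , drop = FALSE]
  sig <- sig[order(sig$qvalue, sig$p_beta_adjusted), , drop = FALSE]
  attr(sig, "qvalue_fit") <- qv
  sig
}

#' Cis-QTL mapping across a phenotype matrix
#'
#' Full primary cis pass: for every anchored phenotype, scan the \code{+/-
#' window} cis region, pick the lead variant (smallest p, ties by largest
#' |t| then smallest position), run permutations, fit the beta approximation
#' and compute the phenotype-level adjusted p-value.  Grouped phenotypes
#' (shared \code{group_id}, exon/splice layers) are scanned jointly and
#' reported as one record for the best member.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param phenos A \code{\link{phenotype_matrix}}; values should already be
#'   rank-normalized/imputed.
#' @param covariates Optional covariate matrix.
#' @param window Cis half-width in bp.
#' @param n_perm Permutations per phenotype.
#' @param seed Base seed; each phenotype uses \code{seed + index}.
#' @param group Use group-aware scanning for phenotypes sharing a
#'   \code{group_id}.
#' @return data.frame, one row per phenotype (or group): lead variant,
#'   nominal statistics, \code{p_beta_adjusted}, beta-fit parameters.
#' @export
map_cis <- function(genotypes, phenos, covariates = NULL, window = 1e6,
                    n_perm = 1000L, seed = 1461167480, group = TRUE) {
  stopifnot(inherits(phenos, "PhenotypeMatrix"))
  meta <- phenos$meta
  anchored <- which(!is.na(meta$chrom))
  if (group) {
    key <- ifelse(!is.na(meta$group_id), paste0("g:", meta$group_id),
                  paste0("p:", meta$phenotype_id))
  } else {
    key <- paste0("p:", meta$phenotype_id)
  }
  units <- split(anchored, key[anchored])
  res <- vector("list", length(units))
  for (i in seq_along(units)) {
    idx <- units[[i]]
    w <- cis_window(genotypes, meta$chrom[idx[1]], meta$tss[idx[1]], window)
    if (length(w$variant_id) == 0L) next
    best <- NULL
    for (j in idx) {
      sc <- nominal_scan(genotypes, phenos$values[, j], covariates,
                         w$variant_id)
      if (nrow(sc) == 0L) next
      sc$phenotype_id <- meta$phenotype_id[j]
      b <- sc[order(sc$p_nominal, -abs(sc$t)), , drop = FALSE][1, ]
      if (is.null(best) || b$p_nominal < best$p_nominal ||
          (b$p_nominal == best$p_nominal && abs(b$t) > abs(best$t)))
        best <- b
    }
    if (is.null(best)) next
    minp <- permutation_minp(genotypes, phenos$values[, idx, drop = FALSE],
                             covariates, w$variant_id, n_perm,
                             seed = (seed + i) %% .Machine$integer.max)
    fit <- fit_beta_approx(minp)
    res[[i]] <- data.frame(
      phenotype_id = best$phenotype_id, variant_id = best$variant_id,
      beta = best$beta, se = best$se, t = best$t,
      p_nominal = best$p_nominal,
      p_beta_adjusted = adjusted_pvalue(best$p_nominal, fit),
      beta_a = if (isTRUE(fit$fit_ok)) fit$a else NA_real_,
      beta_b = if (isTRUE(fit$fit_ok)) fit$b else NA_real_,
      fit_ok = fit$fit_ok, n = best$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
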
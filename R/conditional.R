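# Forward-backward stepwise discovery of independent QTL signals (allelic
# heterogeneity).  Conditioning on previously discovered signals is done by
# adding their dosages to the covariate matrix; each forward iteration
# re-runs the full window scan with 1000 permutations and accepts the best
# variant only if its beta-adjusted p-value clears the phenotype-level
# threshold.

#' Phenotype-level significance threshold for conditional analysis
#'
#' The maximum beta-adjusted p-value among the phenotypes significant at the
#' given FDR in the primary cis pass (default 1\%): the most lenient
#' adjusted p that was still genome-wide significant, reused as the
#' per-iteration acceptance threshold in the stepwise scans.
#'
#' @param records Primary-pass records (one row per phenotype) with columns
#'   \code{p_beta_adjusted} and, if \code{qvalue} is absent, enough to call
#'   \code{\link{call_cis_qtls}}.
#' @param fdr FDR defining the significant seed set.
#' @return The threshold (scalar).
#' @export
phenotype_level_threshold <- function(records, fdr = 0.01) {
  if (is.null(records$qvalue))
    records <- call_cis_qtls(records, fdr = 1)   # attach q-values, keep all
  sig <- records[records$qvalue <= fdr, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant phenotypes: nothing to condition on")
  max(sig$p_beta_adjusted)
}

# One conditional scan + permutation pass; returns best row with adjusted p.
.conditional_step <- function(genotypes, phenotype, covariates, accepted,
                              variant_ids, n_perm, seed) {
  covs <- covariates
  if (length(accepted)) {
    acc <- genotypes$dosage[, accepted, drop = FALSE]
    covs <- if (is.null(covs)) acc else cbind(covs, acc)
    # drop collinear conditioning columns rather than fail
    d <- .design(nrow(acc), covs, allow_drop = TRUE)
    covs <- d$X[, -1, drop = FALSE]
  }
  cand <- setdiff(variant_ids, accepted)
  if (!length(cand)) return(NULL)
  sc <- nominal_scan(genotypes, phenotype, covs, cand)
  if (nrow(sc) == 0L) return(NULL)
  sc <- sc[order(sc$p_nominal, -abs(sc$t)), , drop = FALSE]
  best <- sc[1, ]
  minp <- suppressWarnings(
    permutation_minp(genotypes, phenotype, covs, cand, n_perm, seed))
  fit <- fit_beta_approx(minp)
  best$p_beta_adjusted <- adjusted_pvalue(best$p_nominal, fit)
  best
}

#' Forward pass of the stepwise conditional scan
#'
#' Iteratively re-scans the window conditioning on all previously accepted
#' variants (their dosages added as covariates), each iteration running a
#' full permutation pass, and accepts the best variant while its
#' beta-adjusted p-value is at or below the phenotype-level threshold.
#' Stops otherwise, or at \code{max_iter}.
#'
#' @inheritParams nominal_scan
#' @param threshold Phenotype-level adjusted-p threshold, see
#'   \code{\link{phenotype_level_threshold}}.
#' @param n_perm Permutations per iteration.
#' @param seed Base seed; iteration i uses \code{seed + i}.
#' @param max_iter Iteration cap.
#' @return Character vector of accepted variant ids, in acceptance order.
#' @export
forward_pass <- function(genotypes, phenotype, covariates = NULL,
                         variant_ids, threshold, n_perm = 1000L,
                         seed = 1L, max_iter = 40L) {
  accepted <- character(0)
  for (it in seq_len(max_iter)) {
    best <- .conditional_step(genotypes, phenotype, covariates, accepted,
                              variant_ids, n_perm,
                              (as.integer(seed) + it) %% .Machine$integer.max)
    if (is.null(best) || best$p_beta_adjusted > threshold) break
    accepted <- c(accepted, best$variant_id)
  }
  accepted
}

#' Backward pass: retest each forward signal against all others
#'
#' Each forward signal is retested by scanning the window while conditioning
#' on all \emph{other} forward signals (plus covariates); it is retained iff
#' its beta-adjusted p-value still clears the threshold, and the best
#' variant of that conditional re-scan is reported as the signal's lead.
#' Ranks are assigned by significance (rank 1 = most significant retained
#' signal, the primary).
#'
#' @inheritParams forward_pass
#' @param forward_set Variant ids accepted by \code{\link{forward_pass}}.
#' @param phenotype_id Id used to label the output.
#' @return data.frame (SignalList): \code{phenotype_id}, \code{variant_id},
#'   \code{rank}, \code{beta}, \code{p_nominal}, \code{p_beta_adjusted},
#'   \code{threshold_used}.
#' @export
backward_pass <- function(genotypes, phenotype, covariates = NULL,
                          forward_set, variant_ids, threshold,
                          n_perm = 1000L, seed = 1L,
                          phenotype_id = "phenotype") {
  stopifnot(length(forward_set) > 0)
  # exactly collinear forward variants (r2 = 1) carry one signal: keep the
  # first of each such pair, otherwise the backward conditioning removes both
  if (length(forward_set) > 1L) {
    keep <- rep(TRUE, length(forward_set))
    for (j in 2:length(forward_set)) {
      for (i in 1:(j - 1)) {
        if (!keep[i]) next
        r <- suppressWarnings(cor(genotypes$dosage[, forward_set[i]],
                                  genotypes$dosage[, forward_set[j]]))
        if (is.finite(r) && r^2 > 1 - 1e-12) { keep[j] <- FALSE; break }
      }
    }
    forward_set <- forward_set[keep]
  }
  kept <- list()
  for (i in seq_along(forward_set)) {
    others <- forward_set[-i]
    best <- .conditional_step(genotypes, phenotype, covariates, others,
                              variant_ids, n_perm,
                              (as.integer(seed) + 100L + i) %% .Machine$integer.max)
    if (!is.null(best) && best$p_beta_adjusted <= threshold)
      kept[[length(kept) + 1L]] <- best
  }
  if (!length(kept))
    return(data.frame(phenotype_id = character(), variant_id = character(),
                      rank = integer(), beta = numeric(),
                      p_nominal = numeric(), p_beta_adjusted = numeric(),
                      threshold_used = numeric()))
  out <- do.call(rbind, kept)
  # two forward signals tagging the same variant collapse to one
  out <- out[!duplicated(out$variant_id), , drop = FALSE]
  out <- out[order(out$p_beta_adjusted, out$p_nominal), , drop = FALSE]
  data.frame(phenotype_id = phenotype_id, variant_id = out$variant_id,
             rank = seq_len(nrow(out)), beta = out$beta,
             p_nominal = out$p_nominal,
             p_beta_adjusted = out$p_beta_adjusted,
             threshold_used = threshold, stringsAsFactors = FALSE)
}

#' Full stepwise conditional analysis for one phenotype
#'
#' Convenience wrapper: forward pass then backward pass.
#'
#' @inheritParams backward_pass
#' @return As \code{\link{backward_pass}}; zero rows when the forward pass
#'   accepts nothing.
#' @export
conditional_signals <- function(genotypes, phenotype, covariates = NULL,
                                variant_ids, threshold, n_perm = 1000L,
                                seed = 1L, max_iter = 40L,
                                phenotype_id = "phenotype") {
  fw <- forward_pass(genotypes, phenotype, covariates, variant_ids,
                     threshold, n_perm, seed, max_iter)
  if (!length(fw))
    return(data.frame(phenotype_id = character(), variant_id = character(),
                      rank = integer(), beta = numeric(),
                      p_nominal = numeric(), p_beta_adjusted = numeric(),
                      threshold_used = numeric()))
  if (length(fw) == 1L) {
    # nothing to condition out: report the forward signal directly
    best <- .conditional_step(genotypes, phenotype, covariates, character(0),
                              variant_ids, n_perm,
                              (as.integer(seed) + 101L) %% .Machine$integer.max)
    return(data.frame(phenotype_id = phenotype_id,
                      variant_id = best$variant_id, rank = 1L,
                      beta = best$beta, p_nominal = best$p_nominal,
                      p_beta_adjusted = best$p_beta_adjusted,
                      threshold_used = threshold, stringsAsFactors = FALSE))
  }
  backward_pass(genotypes, phenotype, covariates, fw, variant_ids,
                threshold, n_perm, seed, phenotype_id)
}
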
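#' Rank-based inverse normal transformation
#'
#' Maps the non-missing values of \code{x} to standard-normal quantiles
#' \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} where \eqn{r} is the rank (ties by
#' average rank) and \eqn{c} the offset.  The default offset 0.5 gives the
#' common eQTL-practice transform \eqn{\Phi^{-1}((r - 0.5)/n)}; \code{offset =
#' 3/8} gives Blom scores.  Missing entries stay missing; a monotone transform
#' of the input leaves the output unchanged.
#'
#' @param x Numeric vector with at least 2 non-missing, non-identical values.
#' @param offset Rank offset c in (0, 1).
#' @return Numeric vector, same length and missingness pattern as \code{x}.
#' @export
rank_normalize <- function(x, offset = 0.5) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2L) stop("need at least 2 non-missing values")
  v <- x[obs]
  if (max(v) == min(v))
    stop("degenerate phenotype: all non-missing values identical")
  r <- rank(v, ties.method = "average")
  out <- x
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Mean imputation of missing measurements
#'
#' Replaces missing entries by the mean of the observed ones (the protocol
#' used for sporadically missing protein measurements); observed entries are
#' untouched.  Refuses vectors missing 50\% or more: those phenotypes should
#' have been removed by \code{\link{filter_phenotypes}}.
#'
#' @param x Numeric vector.
#' @return Numeric vector without missing values.
#' @export
mean_impute <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (mean(miss) >= 0.5)
    stop("missing fraction >= 50%: phenotype should have been filtered out")
  x[miss] <- mean(x[!miss])
  x
}

#' Filter phenotypes by per-layer missingness / detection rules
#'
#' Drops phenotypes violating their layer's rule.  The default rules mirror
#' standard QC: genes/exons/splice phenotypes with more than 50\% zero
#' measurements are removed, and proteins with more than 50\% of samples
#' below the limit of detection (encoded as \code{NA}) are removed.
#'
#' @param phenos A \code{\link{phenotype_matrix}}.
#' @param max_zero_frac Maximum tolerated fraction of exact zeros for
#'   expression-type phenotypes (gene, exon, splice).
#' @param max_missing_frac Maximum tolerated fraction of missing (below-LOD)
#'   values for protein and metabolite phenotypes.
#' @return List with the filtered \code{PhenotypeMatrix} (\code{phenos}) and a
#'   data.frame \code{removed} reporting each dropped phenotype and why.
#' @export
filter_phenotypes <- function(phenos, max_zero_frac = 0.5,
                              max_missing_frac = 0.5) {
  stopifnot(inherits(phenos, "PhenotypeMatrix"))
  V <- phenos$values
  meta <- phenos$meta
  if (ncol(V) == 0L)
    return(list(phenos = phenos,
                removed = data.frame(phenotype_id = character(),
                                     reason = character())))
  zero_frac <- colMeans(V == 0, na.rm = TRUE)
  zero_frac[is.nan(zero_frac)] <- 1
  miss_frac <- colMeans(is.na(V))
  expr <- meta$type %in% c("gene", "exon", "splice")
  drop <- (expr & zero_frac > max_zero_frac) |
    (!expr & miss_frac > max_missing_frac)
  reason <- ifelse(expr, sprintf("zero fraction %.2f > %.2f",
                                 zero_frac, max_zero_frac),
                   sprintf("missing fraction %.2f > %.2f",
                           miss_frac, max_missing_frac))
  removed <- data.frame(phenotype_id = meta$phenotype_id[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  keep <- which(!drop)
  list(phenos = phenotype_matrix(V[, keep, drop = FALSE],
                                 meta[keep, , drop = FALSE]),
       removed = removed)
}

#' Residualize phenotypes on covariates
#'
#' Replaces every phenotype by its least-squares residual on an intercept
#' plus the supplied covariates.  Residuals are exactly orthogonal to the
#' covariate columns and the operation is idempotent.
#'
#' @param phenos A \code{\link{phenotype_matrix}} (no missing values; impute
#'   first) or a plain numeric matrix.
#' @param covariates Numeric matrix samples x covariates, full column rank
#'   after adding an intercept (rank deficiency is an error).
#' @return Same class as \code{phenos}, values replaced by residuals.
#' @export
residualize <- function(phenos, covariates = NULL) {
  if (inherits(phenos, "PhenotypeMatrix")) {
    if (anyNA(phenos$values)) stop("missing values: impute before residualizing")
    res <- .proj_resid(phenos$values, covariates)
    dimnames(res) <- dimnames(phenos$values)
    return(phenotype_matrix(res, phenos$meta))
  }
  M <- as.matrix(phenos)
  if (anyNA(M)) stop("missing values: impute before residualizing")
  res <- .proj_resid(M, covariates)
  dimnames(res) <- dimnames(M)
  res
}

#' Principal components of a phenotype matrix
#'
#' Top-k principal component scores of the column-standardized phenotype
#' matrix, intended as hidden-factor covariates for the cis scans.  Missing
#' entries are mean-imputed before the decomposition.  Score columns are
#' orthonormal.
#'
#' @param phenos A \code{\link{phenotype_matrix}} or numeric matrix.
#' @param k Number of components, \code{k < min(samples, phenotypes)}.
#' @return Numeric matrix samples x k, columns \code{PC1..PCk}.
#' @export
compute_phenotype_pcs <- function(phenos, k) {
  V <- if (inherits(phenos, "PhenotypeMatrix")) phenos$values else as.matrix(phenos)
  if (k >= min(dim(V))) stop("k must be < min(samples, phenotypes)")
  V <- apply(V, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  sds <- apply(V, 2, sd)
  keep <- sds > 0
  Z <- scale(V[, keep, drop = FALSE])
  s <- svd(Z, nu = k, nv = 0)
  scores <- s$u[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(V)
  scores
}

#' Default phenotype-PC counts per layer
#'
#' The number of phenotype principal components used as covariates in the cis
#' scans, per phenotype layer: 60 for gene expression, 55 for exons, 20 for
#' splice phenotypes and 10 for proteins.
#'
#' @return Named integer vector.
#' @export
default_pc_counts <- function() {
  c(gene = 60L, exon = 55L, splice = 20L, protein = 10L)
}
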
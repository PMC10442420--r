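# Shared linear-association machinery.  All scans project the covariates out
# of both phenotype and dosage once (Frisch-Waugh) and then work with plain
# cross-products, so permutations never refit the covariate model.

# Design matrix with intercept; drops linearly dependent columns via pivoted QR.
.design <- function(n, covariates = NULL, allow_drop = FALSE) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    if (!allow_drop) stop("rank-deficient covariates (after adding intercept)")
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(X)
  }
  list(X = X, qr = qr_x)
}

# Residualize the columns of M on [1 | covariates].
.proj_resid <- function(M, covariates = NULL, allow_drop = FALSE) {
  M <- as.matrix(M)
  d <- .design(nrow(M), covariates, allow_drop = allow_drop)
  Q <- qr.Q(d$qr)
  M - Q %*% crossprod(Q, M)
}

# Core scan on pre-residualized data.  Gr: n x m residualized dosages,
# yr: residualized phenotype, df: residual degrees of freedom.
.scan_core <- function(Gr, yr, df) {
  sg2 <- colSums(Gr^2)
  sy2 <- sum(yr^2)
  keep <- sg2 > 1e-12 * nrow(Gr)
  sxy <- as.vector(crossprod(Gr, yr))
  r <- sxy / sqrt(sg2 * sy2)
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  beta <- sxy / sg2
  se <- ifelse(tval == 0, sqrt(sy2 / sg2 / df), abs(beta / tval))
  p <- 2 * pt(-abs(tval), df)
  list(beta = beta, se = se, t = tval, p = p, keep = keep, r = r)
}

#' Nominal linear-regression association scan
#'
#' Tests one phenotype against each variant in a window by simple linear
#' regression after projecting the covariates (plus an intercept) out of both
#' phenotype and dosage.  The residual degrees of freedom are
#' \code{n - n_covariates - 2}, matching a joint fit of intercept, covariates
#' and dosage.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param phenotype Numeric vector, one value per sample (no missing values;
#'   impute or drop upstream).
#' @param covariates Optional numeric matrix samples x covariates.
#' @param variant_ids Variants to test; default all.
#' @return data.frame with one row per tested variant: \code{variant_id},
#'   \code{beta}, \code{se}, \code{t}, \code{p_nominal}, \code{df}, \code{n}.
#'   Variants with zero dosage variance after projection are skipped.
#' @export
nominal_scan <- function(genotypes, phenotype, covariates = NULL,
                         variant_ids = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  G <- genotypes$dosage
  if (!is.null(variant_ids)) {
    idx <- match(variant_ids, colnames(G))
    if (anyNA(idx)) stop("unknown variant id(s) in window")
    G <- G[, idx, drop = FALSE]
  }
  if (ncol(G) == 0L) stop("empty window: no variants to test")
  n <- nrow(G)
  stopifnot(length(phenotype) == n)
  if (anyNA(phenotype)) stop("phenotype contains missing values")
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - ncov - 2L
  Gr <- .proj_resid(G, covariates)
  yr <- .proj_resid(phenotype, covariates)
  sc <- .scan_core(Gr, yr, df)
  out <- data.frame(variant_id = colnames(G), beta = sc$beta, se = sc$se,
                    t = sc$t, p_nominal = sc$p, df = df, n = n,
                    stringsAsFactors = FALSE)
  out[sc$keep, , drop = FALSE]
}

#' Per-permutation minimum p-values for a window
#'
#' Permutes the sample labels of the residualized phenotype(s) and records,
#' for each permutation, the minimum nominal p-value across all variants in
#' the window (and, when a phenotype group is supplied, across all group
#' members), i.e. the null distribution of the windows's best association.
#'
#' @inheritParams nominal_scan
#' @param phenotype Numeric vector, or a samples x phenotypes matrix for a
#'   phenotype group anchored at one TSS (exon/splice grouping): the minimum
#'   is then taken across all member phenotypes and all variants.
#' @param n_perm Number of permutations (>= 50; fewer makes the downstream
#'   beta fit unstable and raises a warning).
#' @param seed Integer seed; identical seeds give identical permutations.
#' @return Numeric vector of length \code{n_perm} of minimum p-values.
#' @export
permutation_minp <- function(genotypes, phenotype, covariates = NULL,
                             variant_ids = NULL, n_perm = 1000L,
                             seed = 1L) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (n_perm < 50L)
    warning("n_perm < 50: beta-approximation fit will be unstable")
  G <- genotypes$dosage
  if (!is.null(variant_ids)) {
    idx <- match(variant_ids, colnames(G))
    if (anyNA(idx)) stop("unknown variant id(s) in window")
    G <- G[, idx, drop = FALSE]
  }
  Y <- as.matrix(phenotype)
  n <- nrow(G)
  stopifnot(nrow(Y) == n)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - ncov - 2L
  Gr <- .proj_resid(G, covariates)
  Yr <- .proj_resid(Y, covariates)
  sg <- sqrt(colSums(Gr^2))
  okg <- sg > 1e-12 * n
  Gs <- sweep(Gr[, okg, drop = FALSE], 2, sg[okg], "/")
  sy <- sqrt(colSums(Yr^2))
  Ys <- sweep(Yr, 2, pmax(sy, .Machine$double.eps), "/")
  set.seed(as.integer(seed))
  perm_idx <- replicate(n_perm, sample.int(n))   # n x n_perm
  max_r2 <- rep(0, n_perm)
  for (j in seq_len(ncol(Ys))) {
    Yp <- matrix(Ys[, j][perm_idx], nrow = n)    # permuted copies
    R <- crossprod(Gs, Yp)                       # m x n_perm correlations
    max_r2 <- pmax(max_r2, apply(R^2, 2, max))
  }
  max_r2 <- pmin(max_r2, 1)
  tmax <- sqrt(max_r2 * df / pmax(1 - max_r2, .Machine$double.eps))
  2 * pt(-tmax, df)
}
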
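test_that("nominal scan matches the closed-form OLS oracle", {
  g <- make_geno(6, 1, seed = 1)
  # force a polymorphic 6-sample dosage
  g$dosage[, 1] <- c(0, 1, 2, 1, 0, 2)
  y <- c(0.3, 1.2, 2.1, 0.8, -0.2, 2.6)
  sc <- nominal_scan(g, y)
  o <- ols_oracle(g$dosage[, 1], y)
  expect_equal(sc$beta, o$slope, tolerance = 1e-12)
  expect_equal(sc$se, o$se, tolerance = 1e-12)
  expect_equal(sc$p_nominal, o$p, tolerance = 1e-12)
  expect_equal(sc$df, 4)
})

test_that("a perfect fit drives the p-value below 1e-300", {
  g <- make_geno(100, 1, seed = 2)
  sc <- nominal_scan(g, as.numeric(g$dosage[, 1]))
  expect_lt(sc$p_nominal, 1e-300)
})

test_that("null nominal p-values are uniform (KS over 1000 replicates)", {
  g <- make_geno(1000, 1, seed = 3)
  # 1000 independent null phenotypes against the same SNP, vectorized
  set.seed(4)
  Y <- matrix(rnorm(1000 * 1000), 1000)
  p <- vapply(seq_len(1000), function(i)
    nominal_scan(g, Y[, i])$p_nominal, numeric(1))
  ks <- suppressWarnings(ks.test(p, punif))
  expect_gt(ks$p.value, 0.01)
})

test_that("covariate projection uses Frisch-Waugh degrees of freedom", {
  set.seed(5)
  g <- make_geno(200, 1, seed = 5)
  covs <- cbind(rnorm(200), rnorm(200))
  y <- rnorm(200) + 0.5 * covs[, 1]
  sc <- nominal_scan(g, y, covs)
  expect_equal(sc$df, 200 - 2 - 2)
  # oracle: full joint regression
  fit <- summary(lm(y ~ g$dosage[, 1] + covs))
  expect_equal(sc$beta, unname(coef(fit)[2, 1]), tolerance = 1e-10)
  expect_equal(sc$p_nominal, unname(coef(fit)[2, 4]), tolerance = 1e-10)
})

test_that("monomorphic variants are skipped", {
  g <- make_geno(50, 2, seed = 6)
  g$dosage[, 2] <- 1L
  sc <- nominal_scan(g, rnorm(50))
  expect_identical(sc$variant_id, "v001")
})

test_that("permutation minima follow order-statistic laws", {
  # single SNP: min-p is just one null p -> Uniform(0,1)
  g1 <- make_geno(300, 1, seed = 7)
  set.seed(8); y <- rnorm(300)
  mp1 <- permutation_minp(g1, y, n_perm = 400, seed = 9)
  expect_gt(suppressWarnings(ks.test(mp1, punif)$p.value), 0.01)
  # K = 10 independent SNPs: min-p ~ Beta(1, 10)
  g10 <- make_geno(300, 10, seed = 10)
  mp10 <- permutation_minp(g10, y, n_perm = 600, seed = 11)
  expect_gt(suppressWarnings(
    ks.test(mp10, pbeta, 1, 10)$p.value), 0.005)
  # determinism
  expect_identical(permutation_minp(g10, y, n_perm = 100, seed = 12),
                   permutation_minp(g10, y, n_perm = 100, seed = 12))
  expect_warning(permutation_minp(g1, y, n_perm = 49, seed = 1), "unstable")
})

test_that("beta fit recovers known beta laws from sampled minima", {
  set.seed(13)
  fit_u <- fit_beta_approx(runif(1000))
  expect_true(fit_u$fit_ok)
  expect_equal(fit_u$a, 1, tolerance = 0.2)
  expect_equal(fit_u$b, 1, tolerance = 0.2)
  fit_b <- fit_beta_approx(rbeta(1000, 1, 10))
  expect_true(fit_b$fit_ok)
  expect_gte(fit_b$b, 8); expect_lte(fit_b$b, 12)
  # MLE stationarity: digamma conditions hold at the optimum
  x <- fit_b$minp
  B <- length(x)
  g1 <- sum(log(x)) + B * (digamma(fit_b$a + fit_b$b) - digamma(fit_b$a))
  g2 <- sum(log1p(-x)) + B * (digamma(fit_b$a + fit_b$b) - digamma(fit_b$b))
  expect_lt(max(abs(c(g1, g2))) / B, 1e-6)
  # degenerate input
  expect_false(fit_beta_approx(rep(0.5, 100))$fit_ok)
  expect_error(fit_beta_approx(runif(10)), "50")
})

test_that("adjusted p-values follow the fitted beta CDF", {
  unit <- structure(list(a = 1, b = 1, n_perm = 1000, loglik = 0,
                         fit_ok = TRUE, minp = numeric(0)),
                    class = "BetaApproxFit")
  expect_equal(adjusted_pvalue(c(0.01, 0.5, 1), unit), c(0.01, 0.5, 1))
  b10 <- structure(list(a = 1, b = 10, n_perm = 1000, loglik = 0,
                        fit_ok = TRUE, minp = numeric(0)),
                   class = "BetaApproxFit")
  expect_equal(adjusted_pvalue(0.01, b10), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(adjusted_pvalue(1, b10), 1)
  # monotone in the nominal p for any valid fit
  set.seed(14)
  fit <- fit_beta_approx(rbeta(500, 1.3, 7))
  grid <- sort(runif(50))
  expect_true(all(diff(adjusted_pvalue(grid, fit)) >= 0))
  # empirical fallback when the fit failed
  bad <- structure(list(a = NA, b = NA, n_perm = 99, loglik = NA,
                        fit_ok = FALSE, minp = seq(0.01, 0.99, 0.01)),
                   class = "BetaApproxFit")
  expect_equal(adjusted_pvalue(0.005, bad), 1 / 100)
  expect_equal(adjusted_pvalue(1, bad), 1)
})

test_that("empirical and beta-approximation adjusted p agree", {
  g <- make_geno(300, 15, seed = 15)
  set.seed(16); y <- rnorm(300)
  mp <- permutation_minp(g, y, n_perm = 1000, seed = 17)
  fit <- fit_beta_approx(mp)
  grid <- 10^seq(-4, -0.2, length.out = 25)
  emp <- vapply(grid, function(p) (1 + sum(mp <= p)) / 1001, numeric(1))
  bet <- adjusted_pvalue(grid, fit)
  expect_gt(cor(emp, bet, method = "spearman"), 0.99)
})

test_that("Storey q-values match their defining formulas", {
  # uniform grid: pi0 ~ 1
  p_grid <- seq(0.005, 0.995, by = 0.01)
  qv <- storey_qvalue(p_grid)
  expect_gte(qv$pi0, 0.95); expect_lte(qv$pi0, 1)
  expect_lte(qv$pi1, 0.05)
  # all-signal limit
  qs <- storey_qvalue(rep(1e-12, 100))
  expect_true(all(qs$qvalues <= 1e-10))
  # 5-element vector vs hand enumeration of the step-up formula
  p5 <- c(0.01, 0.40, 0.02, 0.90, 0.30)
  qv5 <- storey_qvalue(p5)
  m <- 5
  pi0 <- min(max(sum(p5 > 0.5) / (m * 0.5), 0.001), 1)
  ps <- sort(p5)
  qs_hand <- pi0 * m * ps / seq_len(m)
  for (i in (m - 1):1) qs_hand[i] <- min(qs_hand[i], qs_hand[i + 1])
  expect_equal(sort(qv5$qvalues), pmin(qs_hand, 1), tolerance = 1e-12)
  expect_equal(qv5$pi0, pi0)
  # q-values monotone along sorted p
  set.seed(18)
  pr <- c(runif(300), rbeta(100, 0.5, 20))
  qr <- storey_qvalue(pr)
  o <- order(pr)
  expect_true(all(diff(qr$qvalues[o]) >= -1e-12))
  expect_true(all(qr$qvalues >= 0 & qr$qvalues <= 1))
})

test_that("cis QTL calling respects the FDR cutoff", {
  rec <- data.frame(phenotype_id = paste0("P", 1:200),
                    variant_id = paste0("v", 1:200),
                    p_beta_adjusted = c(rep(1e-8, 50), runif(150)))
  expect_equal(nrow(call_cis_qtls(rec, fdr = 0)), 0)
  sig <- call_cis_qtls(rec, fdr = 0.05)
  expect_true(all(sig$qvalue <= 0.05))
  expect_true(all(paste0("P", 1:50) %in% sig$phenotype_id))
})

test_that("cis windows clip at the chromosome start and anchor correctly", {
  g <- make_geno(10, 5, seed = 19, spacing = 6e5, start = 1e5)
  w <- cis_window(g, "1", tss = 7e5, window = 1e6)
  expect_equal(w$start, 1)   # clipped
  v <- g$variants
  expect_setequal(w$variant_id,
                  v$variant_id[abs(v$pos - 7e5) <= 1e6])
  expect_length(cis_window(g, "2", 7e5)$variant_id, 0)
})
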
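test_that("pi1 is near 0 under the null and near 1 under all-signal", {
  set.seed(51)
  est0 <- pi1_sharing(runif(1000), n_boot = 20, seed = 52)
  expect_gte(est0$pi1, 0); expect_lte(est0$pi1, 0.05)
  est1 <- pi1_sharing(rep(1e-8, 200), n_boot = 20, seed = 53)
  expect_gt(est1$pi1, 0.95)
  expect_error(pi1_sharing(numeric(0)), "empty")
})

test_that("pi1 recovers a planted mixture proportion", {
  set.seed(54)
  reps <- vapply(1:20, function(i) {
    p <- c(rbeta(700, 0.5, 50), runif(300))
    pi1_sharing(p, n_boot = 2, seed = i)$pi1
  }, numeric(1))
  expect_gte(mean(reps), 0.6)
  expect_lte(mean(reps), 0.8)
})

test_that("pi1 bootstrap interval brackets the point estimate", {
  set.seed(55)
  p <- c(rbeta(300, 0.5, 50), runif(700))
  est <- pi1_sharing(p, n_boot = 100, seed = 56)
  expect_lte(est$ci_low, est$pi1)
  expect_gte(est$ci_high, est$pi1)
  expect_gte(est$ci_low, 0); expect_lte(est$ci_high, 1)
})

test_that("per-SNP p-value combination follows product and Fisher forms", {
  expect_equal(combine_snp_pvalues(0.3, "product"), 0.3)
  expect_equal(combine_snp_pvalues(0.3, "fisher"), 0.3, tolerance = 1e-12)
  expect_equal(combine_snp_pvalues(c(0.1, 0.1), "product"), 0.01)
  expect_equal(combine_snp_pvalues(c(0.1, 0.1), "fisher"),
               pchisq(-2 * log(0.01), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(combine_snp_pvalues(c(0.1, 0.1), "fisher"), 0.0561,
               tolerance = 1e-3)
  # product is strictly decreasing when any p < 1 is added
  base <- combine_snp_pvalues(c(0.2, 0.4), "product")
  expect_lt(combine_snp_pvalues(c(0.2, 0.4, 0.99), "product"), base)
  # zero p clamped, not -Inf/NaN
  expect_gt(combine_snp_pvalues(c(0, 0.5), "product"), 0)
})

test_that("Fisher enrichment matches the sample OR and exact enumeration", {
  r <- fisher_enrichment(rbind(c(10, 20), c(5, 40)))
  expect_equal(r$odds_ratio, 4.0)
  r2 <- fisher_enrichment(rbind(c(5, 5), c(5, 5)))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
  # brute-force hypergeometric enumeration oracle for the two-sided p
  tab <- rbind(c(8, 2), c(1, 9))
  r3 <- fisher_enrichment(tab)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_brute <- sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
  expect_equal(r3$p_value, p_brute, tolerance = 1e-9)
  # Haldane correction only when a zero cell is present
  rz <- fisher_enrichment(rbind(c(3, 0), c(2, 5)))
  expect_equal(rz$odds_ratio, (3.5 * 5.5) / (0.5 * 2.5))
  expect_error(fisher_enrichment(matrix(0, 2, 2)), "all-zero")
})

test_that("Fisher enrichment equals enumeration across small random tables", {
  set.seed(57)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (all(tab == 0) || sum(tab) > 40) next
    r <- fisher_enrichment(tab)
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n2):min(k, m)
    probs <- dhyper(support, m, n2, k)
    p_brute <- sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
    expect_equal(r$p_value, p_brute, tolerance = 1e-9)
  }
})

test_that("matched subsampling controls power differences", {
  set.seed(58)
  n_large <- 2000; n_small <- 200
  p_large <- rbeta(n_large, 0.3, 10)
  # null: flags independent of significance -> OR ~ 1
  flag_large <- runif(n_large) < 0.2
  flag_small <- runif(n_small) < 0.2
  r0 <- matched_subsample_enrichment(p_large, flag_large, flag_small,
                                     n_draws = 3, seed = 59)
  expect_gt(r0$p_value, 0.001)
  expect_lt(abs(log(r0$odds_ratio)), log(2.5))
  # planted: flags concentrated among the strongest SNPs -> OR > 1
  flag_enr <- rank(p_large) <= 400 & runif(n_large) < 0.6
  r1 <- matched_subsample_enrichment(p_large, flag_enr, flag_small,
                                     n_draws = 3, seed = 60)
  expect_gt(r1$odds_ratio, 1)
  # match_to = full size reproduces the unmatched table
  rfull <- matched_subsample_enrichment(p_large, flag_large, flag_small,
                                        match_to = n_large, seed = 61)
  tab <- rbind(c(sum(flag_large), sum(!flag_large)),
               c(sum(flag_small), sum(!flag_small)))
  expect_equal(rfull$odds_ratio, fisher_enrichment(tab)$odds_ratio)
  expect_error(matched_subsample_enrichment(p_large, flag_large, flag_small,
                                            match_to = n_large + 1),
               "exceeds")
})

test_that("pleiotropy pair statistics detect distance/concordance structure", {
  set.seed(62)
  # discordant pairs systematically farther apart
  pairs <- data.frame(
    tss_distance = c(runif(15, 0, 1e5), runif(15, 5e5, 2e6)),
    sign_concordant = rep(c(TRUE, FALSE), each = 15),
    same_strand = runif(30) < 0.5)
  st <- pleiotropy_pair_stats(pairs)
  expect_lt(st$wilcoxon_distance$p_value, 0.05)
  # identical distributions -> uniform p under repetition (median ~ 0.5)
  ps <- vapply(1:40, function(i) {
    pr <- data.frame(tss_distance = runif(30),
                     sign_concordant = rep(c(TRUE, FALSE), 15),
                     same_strand = runif(30) < 0.5)
    pleiotropy_pair_stats(pr)$wilcoxon_distance$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25); expect_lt(mean(ps), 0.75)
  # strand independent of concordance -> OR near 1 on a large sample
  big <- data.frame(tss_distance = runif(4000),
                    sign_concordant = runif(4000) < 0.5,
                    same_strand = runif(4000) < 0.5)
  st2 <- pleiotropy_pair_stats(big)
  expect_lt(abs(log(st2$strand_or$odds_ratio)), log(1.5))
  expect_error(pleiotropy_pair_stats(
    data.frame(tss_distance = 1:4, sign_concordant = TRUE,
               same_strand = TRUE)), "concordan")
})

test_that("interval assignment follows half-open BED semantics", {
  iv <- data.frame(chrom = "1", start = 100, end = 200, id = "tad1")
  pos <- data.frame(chrom = c("1", "1", "1", "2"),
                    pos = c(150, 200, 99, 150))
  expect_identical(assign_intervals(pos, iv),
                   c("tad1", NA, NA, NA))
  # 1000 random positions vs naive linear-scan oracle
  set.seed(63)
  ivs <- data.frame(chrom = sample(c("1", "2"), 40, TRUE),
                    start = sample.int(1000, 40))
  ivs$end <- ivs$start + sample.int(100, 40)
  ivs$id <- paste0("iv", seq_len(40))
  ivs <- ivs[order(ivs$chrom, ivs$start), ]
  qs <- data.frame(chrom = sample(c("1", "2"), 1000, TRUE),
                   pos = sample.int(1100, 1000, TRUE))
  got <- assign_intervals(qs, ivs)
  naive <- vapply(seq_len(1000), function(i) {
    hit <- which(ivs$chrom == qs$chrom[i] & ivs$start <= qs$pos[i] &
                   qs$pos[i] < ivs$end)
    if (length(hit)) ivs$id[hit[1]] else NA_character_
  }, character(1))
  expect_identical(got, naive)
  expect_error(assign_intervals(pos, data.frame(chrom = "1", start = 5,
                                                end = 2, id = "x")),
               "malformed")
})
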
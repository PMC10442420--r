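test_that("HWE genotype class frequencies match the closed form", {
  g <- simulate_genotypes(variant_specs("v1", "1", 100, 0.5), 100000,
                          seed = 11)
  freq <- tabulate(g$dosage[, 1] + 1L, 3) / 100000
  # MAF 0.5 under HWE: {0.25, 0.5, 0.25}; MC error ~ 3*sqrt(pq/n) < 0.005
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("generator is deterministic and validates its inputs", {
  sp <- variant_specs(c("a", "b"), "1", c(100, 200), c(0.2, 0.4))
  expect_identical(simulate_genotypes(sp, 50, seed = 3)$dosage,
                   simulate_genotypes(sp, 50, seed = 3)$dosage)
  expect_error(simulate_genotypes(
    variant_specs("a", "1", 100, 0.7), 50), "maf")
  expect_error(simulate_genotypes(
    variant_specs(c("a", "a"), "1", c(1, 2), 0.3), 50), "duplicate")
  expect_error(simulate_genotypes(
    variant_specs(c("a", "b"), "1", c(200, 100), 0.3), 50), "increasing")
})

test_that("LD blocks hit the target pairwise r2", {
  sp <- variant_specs(c("a", "b"), "1", c(100, 200), 0.3,
                      block_id = 1, block_r2 = 0.9)
  g <- simulate_genotypes(sp, 2000, seed = 21)
  r2 <- cor(g$dosage[, "a"], g$dosage[, "b"])^2   # realized-dosage oracle
  expect_gte(r2, 0.8)
  expect_lte(r2, 1.0)
})

test_that("realized MAF stays within 3 binomial SDs of the spec", {
  mafs <- c(0.05, 0.1, 0.25, 0.4, 0.5)
  n <- 2000
  sp <- variant_specs(paste0("v", seq_along(mafs)), "1",
                      100 * seq_along(mafs), mafs)
  g <- simulate_genotypes(sp, n, seed = 31)
  realized <- colMeans(g$dosage) / 2
  tol <- 3 * sqrt(mafs * (1 - mafs) / (2 * n))
  expect_true(all(abs(realized - mafs) <= tol))
})

test_that("zero-noise cis effect reproduces the dosage exactly", {
  g <- make_geno(200, 1, seed = 41)
  meta <- data.frame(phenotype_id = "P", type = "gene", chrom = NA, tss = NA)
  sim <- simulate_multiomics(g, meta, planted_effects("P", "v001", 1, "cis"),
                             noise_sd = 0, standardize = FALSE, seed = 42)
  expect_equal(sim$phenos$values[, "P"], std_dosage(g, "v001"),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mediated trans effects compose as the product of path slopes", {
  g <- make_geno(4000, 1, seed = 51)
  meta <- data.frame(phenotype_id = c("M", "T"), type = "gene",
                     chrom = NA, tss = NA)
  ef <- rbind(planted_effects("M", "v001", 0.5, "cis"),
              planted_effects("T", "v001", 0.8, "trans_mediated",
                              mediator_id = "M"))
  sim <- simulate_multiomics(g, meta, ef, standardize = FALSE, seed = 52)
  o <- ols_oracle(std_dosage(g, "v001"), sim$phenos$values[, "T"])
  expect_equal(o$slope, 0.5 * 0.8, tolerance = 0.1)   # path product
})

test_that("three cis effects on one gene are all detectable marginally", {
  ms <- make_multisignal(1000, k = 3, beta = 0.5, seed = 61)
  sc <- nominal_scan(ms$geno, ms$y)
  hits <- sc$variant_id[sc$p_nominal < 1e-6]
  expect_gte(length(hits), 3)
  expect_true(all(ms$lead %in% hits))
})

test_that("variance attributable to planted SNPs matches the truth", {
  k <- 2; beta <- 0.5
  ms <- make_multisignal(5000, k = k, beta = beta, n_decoy = 0, seed = 71)
  y <- ms$y
  G <- scale(ms$geno$dosage[, ms$lead])
  fit <- lm(y ~ G)
  genetic_var <- var(fitted(fit))
  expect_equal(genetic_var, k * beta^2, tolerance = 0.1)   # within 10%
})

test_that("cyclic mediation graphs are rejected", {
  g <- make_geno(100, 1, seed = 81)
  meta <- data.frame(phenotype_id = c("A", "B"), type = "gene",
                     chrom = NA, tss = NA)
  ef <- rbind(planted_effects("A", "v001", 0.5, "trans_mediated",
                              mediator_id = "B"),
              planted_effects("B", "v001", 0.5, "trans_mediated",
                              mediator_id = "A"))
  expect_error(simulate_multiomics(g, meta, ef, seed = 1), "cyclic")
})

test_that("planted trios obey their factorization", {
  # independent: no P1-P2 correlation given the SNP
  tr <- plant_trio("independent", 2000, beta_snp = 0.5, seed = 91)
  r <- residuals(lm(tr$phenos$values[, "P1"] ~ tr$genotypes$dosage[, 1]))
  s <- residuals(lm(tr$phenos$values[, "P2"] ~ tr$genotypes$dosage[, 1]))
  expect_lt(abs(cor(r, s)), 0.08)
  # direction1: P2-SNP slope is the path product (attenuation oracle)
  tr1 <- plant_trio("direction1", 4000, beta_snp = 0.5, beta_path = 0.8,
                    seed = 92)
  o <- ols_oracle(std_dosage(tr1$genotypes, "snp1"),
                  tr1$phenos$values[, "P2"])
  expect_equal(o$slope, 0.4, tolerance = 0.1)
  # two-SNP pair realizes the requested LD
  tr2 <- plant_trio("independent", 2000, 0.5, two_snp = TRUE, ld_r2 = 0.95,
                    seed = 93)
  expect_gte(ld_r2(tr2$genotypes$dosage[, "snp1"],
                   tr2$genotypes$dosage[, "snp2"]), 0.9)
  expect_error(plant_trio("independent", 100, 0.5, two_snp = TRUE,
                          ld_r2 = 0.5), "ld_r2")
  expect_error(plant_trio("sideways", 100, 0.5), "arg")
})

test_that("fixtures round-trip losslessly through the readers", {
  st <- simulate_study(n_samples = 40, n_genes = 6, n_proteins = 2,
                       n_metabolites = 2, seed = 101)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(st$genotypes, st$phenos, st$covariates,
                          st$truth, dir)
  g2 <- read_vcf_dosage(paths["vcf"])
  expect_equal(unname(g2$dosage),
               unname(st$genotypes$dosage), ignore_attr = TRUE)
  expect_identical(rownames(g2$dosage), rownames(st$genotypes$dosage))
  p2 <- read_phenotype_bed(paths["bed"])
  expect_equal(p2$values, st$phenos$values, tolerance = 1e-12)
  expect_identical(p2$meta$type, st$phenos$meta$type)
  c2 <- read_covariates(paths["cov"])
  expect_equal(unname(c2), unname(st$covariates[, colnames(c2)]),
               tolerance = 1e-12)
})

test_that("unanchored phenotypes use the sentinel chromosome in BED output", {
  st <- simulate_study(n_samples = 30, n_genes = 4, n_proteins = 1,
                       n_metabolites = 2, seed = 111)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(st$genotypes, st$phenos, out_dir = dir)
  bed <- data.table::fread(paths["bed"], na.strings = NULL)
  met <- bed[bed$type == "metabolite", ]
  expect_true(all(met[[1]] == "NA"))   # sentinel chromosome literal
  p2 <- read_phenotype_bed(paths["bed"])
  expect_true(all(is.na(p2$meta$chrom[p2$meta$type == "metabolite"])))
})

test_that("VCF dimensions match samples and variants", {
  g <- make_geno(3, 2, seed = 121)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)                       # one data line per variant
  expect_length(strsplit(body[1], "\t")[[1]], 9 + 3)  # 3 genotype columns
})
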
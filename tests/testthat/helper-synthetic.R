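# Shared fixture builders; everything is generated in code at test time.

# Unlinked variants evenly spaced on one chromosome.
make_geno <- function(n, m, maf = 0.3, chrom = "1", seed = 1,
                      spacing = 1e4, start = 1e5) {
  specs <- variant_specs(sprintf("v%03d", seq_len(m)), chrom,
                         start + spacing * (seq_len(m) - 1L),
                         rep_len(maf, m))
  simulate_genotypes(specs, n, seed = seed)
}

# Standardized dosage vector.
std_dosage <- function(geno, id) as.vector(scale(geno$dosage[, id]))

# Hand-rolled OLS slope/se/t/p oracle (simple regression, no covariates).
ols_oracle <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  res <- yc - slope * xc
  df <- n - 2
  se <- sqrt(sum(res^2) / df / sum(xc^2))
  t <- slope / se
  list(slope = slope, se = se, t = t, p = 2 * pt(-abs(t), df))
}

# Genotype matrix with k planted cis signals in separate tight LD blocks
# plus unlinked decoys, and the phenotype carrying those signals.
make_multisignal <- function(n, k = 3, beta = 0.5, n_decoy = 20,
                             block_size = 4, block_r2 = 0.95, seed = 1) {
  m <- k * block_size + n_decoy
  pos <- 1e5 + 2e4 * (seq_len(m) - 1L)
  block_id <- c(rep(seq_len(k), each = block_size), rep(NA, n_decoy))
  block_r2v <- c(rep(block_r2, k * block_size), rep(NA, n_decoy))
  specs <- variant_specs(sprintf("v%03d", seq_len(m)), "1", pos,
                         maf = 0.3, block_id = block_id,
                         block_r2 = block_r2v)
  geno <- simulate_genotypes(specs, n, seed = seed)
  set.seed(seed + 1000)
  lead <- sprintf("v%03d", (seq_len(k) - 1L) * block_size + 1L)
  y <- rnorm(n)
  for (v in lead) y <- y + beta * std_dosage(geno, v)
  list(geno = geno, y = y, lead = lead,
       variant_ids = specs$variant_id)
}
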
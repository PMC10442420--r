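# omicqtl

Multi-omics QTL mapping, independent-signal discovery, causal trios,
colocalization and regulatory networks, in R.

## The problem

Population-scale molecular studies measure several phenotype layers — gene
expression, circulating proteins, metabolites — on the same donors and ask
how genetic variation propagates through them: which variants regulate
which molecules locally (cis) and at a distance (trans), how many
independent signals act on one phenotype (allelic heterogeneity), which
variants act on several phenotypes (pleiotropy), whether a shared
association is mediated by one of the two molecules or hits both
independently, and whether QTL signals share causal variants with GWAS
hits. `omicqtl` implements that analysis chain for researchers in
statistical genetics who want a tested, reproducible, desk-scale
implementation of each stage, together with a synthetic multi-omics
generator with planted ground truth so every stage can be validated
without access-controlled cohort data.

## The statistics at the core

* **Cis mapping.** Linear regression of phenotype on dosage with
  covariates projected out of both (Frisch–Waugh), windows of ±1 Mb
  around the TSS. Phenotype-level multiple testing by permutation: the
  per-permutation minimum p-values of a window are fitted by a
  maximum-likelihood Beta(a, b) and the adjusted p-value is the fitted CDF
  *I<sub>p</sub>(a, b)* at the observed best p (for K independent tests
  this reproduces 1 − (1 − p)<sup>K</sup>). Genome-wide FDR by Storey
  q-values: π̂₀(λ) = #{p > λ}/(m(1 − λ)), spline-smoothed, then the
  step-up q<sub>(i)</sub> = min<sub>j≥i</sub> π̂₀ m p<sub>(j)</sub>/j.
* **Independent signals.** Forward–backward stepwise scans conditioning on
  previously discovered variants as covariates, each iteration re-permuted;
  the acceptance threshold is the largest beta-adjusted p among phenotypes
  significant at FDR 1%.
* **Trans mapping.** Genome-wide scans excluding ±5 Mb around the anchor
  (metabolites unanchored, no exclusion), storing p < 1e-4, with empirical
  permutation thresholds (50 permutations for expression, 100 for
  proteins/metabolites) and region-based secondary signals.
* **Sharing and enrichment.** π1 = 1 − π̂₀ of target-set p-values,
  bootstrap CIs; Fisher exact enrichments; Wilcoxon pleiotropy-pair
  statistics; per-SNP p-value combination.
* **Causal trios.** For a SNP associated with two phenotypes, Gaussian
  Bayesian-network likelihoods of direction 1 (SNP→P1→P2), direction 2
  (SNP→P2→P1) and independent (SNP→P1, SNP→P2); models compared by
  score = log L − (k/2) ln n with a conclusiveness margin δ = 10.
* **Colocalization.** Wakefield log-ABFs (W = 0.15), single-causal-variant
  posteriors PP0–PP4 in log space, and the renormalized sharing ratio
  P(H4′) = PP4/(PP3 + PP4).
* **Networks.** Bipartite SNP→phenotype graphs from deduplicated QTL
  records, union–find components, GWAS-catalog annotation and
  connectivity/enrichment tests.

See `vignettes/multiomics-qtl-methods.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(omicqtl)

# a synthetic cohort: 500 samples, 2 chromosomes, planted architecture
study <- simulate_study(n_samples = 500, seed = 20)
study$genotypes
#> GenotypeMatrix: 500 samples x 180 variants (2 chromosome(s))
study$phenos
#> PhenotypeMatrix: 500 samples x 48 phenotypes (gene=30, metabolite=8, protein=10)

# preprocessing + cis mapping + conditional signals, end to end
res <- run_cis_pipeline(study, n_perm = 200, seed = 21)
nrow(res$significant)   # phenotypes with a cis-QTL at FDR 5%
#> [1] 32
head(res$significant[, c("phenotype_id", "variant_id", "beta",
                         "p_beta_adjusted", "qvalue")], 3)
#>    phenotype_id variant_id      beta p_beta_adjusted       qvalue
#> 10       GENE10   rs_g10_1 1.0787395    6.872407e-58 5.497925e-57
#> 13       GENE13   rs_g13_1 0.8641389    4.078764e-57 1.631506e-56
#> 7        GENE07   rs_g07_1 1.2433097    1.351263e-50 3.603368e-50

# allelic heterogeneity: independent signals per phenotype (planted: 1-3)
table(table(res$signals$phenotype_id))
#>  1  2  3
#> 10  8  8

# causal inference on a planted mediation trio
tr <- plant_trio("direction1", n_samples = 3000,
                 beta_snp = 0.5, beta_path = 0.8, seed = 22)
score_trio_models(tr$genotypes$dosage[, "snp1"],
                  tr$phenos$values[, "P1"], tr$phenos$values[, "P2"])
#> Trio model fit (n = 3000): best = direction1, margin = 158.88 (conclusive)
#>                loglik k     score
#> direction1  -11237.66 8 -11269.68
#> direction2  -11396.53 8 -11428.56
#> independent -11966.75 8 -11998.78
```

The cis pass finds a QTL for 32 of 40 anchored phenotypes (the generator
plants effects on roughly that many, with β = 0.8 SD), the stepwise scan
recovers the planted 1–3 independent signals per gene, and the trio score
identifies the planted mediation direction with a margin far above the
δ = 10 conclusiveness threshold.

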
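---
title: "Methods: multi-omics QTL mapping, causal trios and regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics QTL mapping, causal trios and regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicqtl)
```

# Scope

`omicqtl` implements a complete desk-scale pipeline for the genetic analysis
of multi-layer molecular phenotypes measured on one cohort: gene expression,
circulating proteins and metabolites. The stages are

1. preprocessing (filtering, mean imputation, rank-inverse-normal
   transformation, covariate residualization, phenotype PCs);
2. cis-QTL mapping with permutation-based beta-approximation adjusted
   p-values and Storey q-values;
3. forward–backward stepwise discovery of multiple independent signals per
   phenotype (allelic heterogeneity);
4. genome-wide trans-QTL discovery with a distance exclusion, artifact
   filters, empirical permutation thresholds and region-based secondary
   signals;
5. sharing and enrichment statistics (π1, per-SNP p-value combination,
   Fisher enrichments, pleiotropy pair statistics, interval annotation);
6. causal inference on SNP–phenotype–phenotype trios with Gaussian
   Bayesian-network scores;
7. approximate-Bayes-factor colocalization with the renormalized sharing
   ratio P(H4′);
8. typed SNP→phenotype network construction with GWAS annotation.

Because the cohort data such analyses are usually run on is access
controlled, the package ships a synthetic-data module that plants a known
regulatory architecture; every statistical property claimed for the pipeline
is demonstrated on that generator by the test-suite and by
`scripts/acceptance.R`.

# The association model

All scans use the linear model
$y_i = \alpha + \beta g_i + \gamma^\top c_i + \varepsilon_i$,
where $g_i \in \{0,1,2\}$ is the alternate-allele dosage and $c_i$ the
covariates. Covariates are projected out of both $y$ and $g$ once per
window (Frisch–Waugh), after which slope, SE, t and p follow from plain
cross-products with residual degrees of freedom $n - (\#\text{covariates}) - 2$.
This matters for permutations: the phenotype *residuals* are permuted and
the covariate fit is never repeated, so a 1000-permutation window scan is a
single matrix product per phenotype.

## Phenotype-level multiple testing: the beta approximation

For each phenotype the null distribution of the window's *best* nominal p
is estimated from the per-permutation minimum p-values and summarized by a
maximum-likelihood Beta(a, b) fit (method-of-moments initialization, BFGS
on log-parameters with analytic digamma gradients). The adjusted p-value is
the fitted beta CDF at the observed best p, $I_p(a,b)$. For a window of K
independent variants the truth is $1-(1-p)^K$, i.e. Beta(1, K); the fit
tracks that law and, more usefully, adapts to the unknown effective number
of tests in windows with LD. The fit is declared unusable (`fit_ok = FALSE`)
when the optimizer fails or the Kolmogorov–Smirnov distance between minima
and fitted beta exceeds 0.2; the empirical permutation p-value
$(1+\#\{m \le p\})/(1+B)$ is then used instead. The nominal degrees of
freedom are used throughout; a permutation-based effective-df re-estimation
would be a second-order refinement at the sample sizes this pipeline
targets.

## Genome-wide FDR: Storey q-values

$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ is computed on the
grid $\lambda = 0.05, \ldots, 0.95$, smoothed by a cubic spline (df = 3) and
read off at the largest $\lambda$; with fewer than 100 p-values the spline
is unreliable and a fixed $\lambda = 0.5$ is used. $\hat\pi_0$ is clamped to
$[0.001, 1]$ so q-values stay finite. q-values are the usual step-up
$\min_{j\ge i} \hat\pi_0\, m\, p_{(j)}/j$. The same machinery provides the
π1 sharing estimate ($\pi_1 = 1-\hat\pi_0$ of the target-set p-values of
discovery-significant pairs) with a percentile bootstrap CI (100 resamples;
the CI method is a package choice — percentile is the least assumption-laden
at these sample sizes).

## Conditional signals

Phenotypes significant at FDR 1% in the primary pass seed the stepwise
scan; the acceptance threshold is the largest beta-adjusted p among that
seed set — the most lenient phenotype-level p that was still genome-wide
significant. The forward stage repeatedly re-scans the window with all
previously accepted variants added to the covariates (a literal reading of
"correcting for previously discovered SNPs") and accepts the best variant
while its adjusted p clears the threshold, capped at 40 iterations. The
backward stage retests each forward variant conditioning on all the others
and reports the best variant of each surviving conditional scan, ranked by
significance. Exactly collinear forward pairs (r² = 1) are collapsed to
their first member before the backward stage — conditioning on a perfect
copy would otherwise annihilate both. Permutation seeds are derived per
iteration (base seed + iteration), so runs are exactly reproducible.

## Trans mapping

Anchored phenotypes are tested against all variants on other chromosomes or
more than 5 Mb from the TSS; metabolites have no anchor and are tested
genome-wide. Only pairs with p < 1e-4 are stored. Phenotype-level
multiple-testing correction is the empirical permutation p-value over
genome-wide minima — 50 permutations for expression, 100 for proteins and
metabolites — with Storey q-values across phenotypes. The empirical reading
is the package default because the adjusted p then sits on the honest
$(B+1)$-grid; a beta-fit variant (`method = "beta"`), which can extrapolate
below $1/(B+1)$, is available since the construction of the phenotype-level
trans threshold admits both readings. Mappability/repeat/cross-mappability
artifact filters are applied from user-supplied annotation tables. Windows
of ±1 Mb around significant trans variants are merged (half-open intervals,
leftmost sweep) into regions, and the cis stepwise machinery is re-run per
region for secondary signals.

# Causal trios

For a variant associated with two phenotypes, three factorizations are
scored on complete cases:

* direction 1: P(P2 | P1) · P(P1 | SNP) · P(SNP)
* direction 2: P(P1 | P2) · P(P2 | SNP) · P(SNP)
* independent: P(P1 | SNP) · P(P2 | SNP) · P(SNP)

with two-SNP variants for lead pairs in LD r² > 0.9 (SNP1 is phenotype 1's
lead, SNP2 phenotype 2's). Gaussian linear conditionals contribute
$-\tfrac n2(\ln 2\pi\hat\sigma^2 + 1)$ with MLE variance and $k =
\#\text{parents} + 2$ parameters; the genotype marginal is a multinomial
over observed classes with $k = \#\text{classes} - 1$. Models are compared
on the scale $\text{score} = \log L - (k/2)\ln n$ and a trio is conclusive
when the best model beats both others by δ = 10 on that scale. The scale
and threshold are package choices: network-scoring software reports BIC up
to a factor of −2 and the margin rule is only meaningful once the scale is
fixed; δ is configurable. In the one-SNP case all three models have equal
k, so score and likelihood orderings coincide — a useful analytic check.
For two-SNP trios the printed factorizations span slightly different
variable sets (direction 1 never mentions SNP2); they are scored exactly as
printed, and a conditioned-on-genotypes variant that drops the P(SNP)
factors is available (`include_snp_marginals = FALSE`) for users who prefer
comparisons over a common variable set. Phenotypes entering trios should be
*pseudo-phenotypes*: residuals on covariates and on all of the phenotype's
other QTL signals (`single_signal_residual`), so each trio isolates one
genetic signal. Samples missing any trio element are dropped.

# Colocalization

Per-SNP evidence is the Wakefield log approximate Bayes factor
$\tfrac12\ln(1-r) + z^2 r/2$, $r = W^2/(W^2+se^2)$, with prior effect SD
W = 0.15 for quantitative traits. Regions are reduced to variants with
p < 0.1 plus everything within 20 kb of the lead. Single-causal-variant
posteriors PP0–PP4 are computed by log-sum-exp over configurations (the
H3 sum over ordered distinct pairs uses the identity
$\sum_{i\ne j} = \sum_i\sum_j - \sum_{i=j}$ in log space), with priors
p1 = p2 = 1e-4, p12 = 1e-5. W and the priors are the conventional
quantitative-trait defaults; the source analyses do not state alternatives.
Because QTL leads are typically pre-selected as trait-associated, the
headline quantity is the renormalized ratio P(H4′) = PP4/(PP3+PP4). When
only p, MAF and n are available, se is reconstructed from the
unit-variance-trait approximation $se = 1/\sqrt{2nf(1-f)}$ and |β| = |z|·se;
when per-SNP n varies, the median n is used.

# Networks

Significant QTL tables become a bipartite directed network (SNP → phenotype,
edge label = association type, duplicates collapsed keeping the best p).
Connected components use union–find with path compression and deterministic
labels (smallest member id); the independent oracle in the tests is
igraph/BFS. Mean connectivity is reported both as 2|E|/|V| and as the mean
number of distinct neighbors — the two definitions differ on multigraph-like
inputs and published "average edges per node" figures are not always
attributable to either, so both are emitted. GWAS annotation joins a
catalog-style table on lead variants; connectivity tests are a Wilcoxon
rank-sum on out-degree (GWAS vs non-GWAS SNPs) and per-layer Fisher
enrichments, with molecular-trait GWAS entries (protein/metabolite GWAS)
excludable to avoid circularity, plus a power-matched variant that keeps
only the top-N most significant SNPs of the larger set.

# The synthetic-data generator

The generator defines the conditions under which the pipeline's properties
are demonstrated:

* **Genotypes** are drawn under Hardy–Weinberg equilibrium at each variant's
  MAF (QC floor MAF > 0.01). LD blocks copy a shared latent haplotype pair
  with per-allele flip probability $\epsilon = 1 - r_2^{1/4}$, giving
  pairwise dosage correlation² equal to the target r₂ in closed form —
  exact when block members share a MAF, which the bundled study enforces.
  No recombination maps or imputation uncertainty are modelled.
* **Phenotypes** are sums of planted effects in phenotype-SD units on the
  standardized dosage, plus covariate loadings and Gaussian noise, built in
  topological order of the mediation graph. Mediated trans effects
  contribute (path slope) × (mediator value), so marginal SNP slopes are
  products of path coefficients. Phenotypes are z-scored after generation
  by default; the closed-form path arithmetic used by several oracles holds
  exactly on the unstandardized scale, so tests that assert slope products
  set `standardize = FALSE`.
* **Layers**: proteins are coupled to their cognate gene (default slope
  0.6) and are the only layer with missingness — MCAR, at most 8.5% per
  protein, mirroring observed protein-panel missingness ceilings;
  metabolites are unanchored. The bundled study
  (`simulate_study()`) plants allelic heterogeneity (1–3 independent cis
  signals per gene), one pleiotropic variant driving three genes (one with
  opposite sign), and a cis-regulated mediator with distal targets.
* **Defaults**: 500 samples, 30 genes on 2 chromosomes, 6-variant LD
  neighbourhoods (r² 0.9) per gene, cis β = 0.8 SD — large enough that a
  desk-scale run shows every qualitative feature (heterogeneity,
  pleiotropy, mediation) without requiring cohort-scale compute.

What the generator does *not* emulate — read counts and their
mean–variance relation, population structure beyond supplied covariates,
batch structure, non-Gaussian assay noise, realistic LD decay — bounds what
green tests prove: they certify the statistical machinery (calibration,
recovery, exactness), not robustness to every artifact of real assays.

# Numerical choices and degenerate inputs

* Permutation minima at exactly 0/1 are clamped to $[1/2B, 1-1/2B]$ before
  the beta fit.
* Monomorphic variants (zero dosage variance after covariate projection)
  are skipped in scans; a trio whose genotype shows a single class is
  rejected.
* Lead-variant ties break by smallest p, then largest |t|, then smallest
  position (windows are position-sorted).
* Rank normalization uses offset 0.5 — $\Phi^{-1}((r-0.5)/n)$ — with ties
  by average rank; Blom's offset is available via `offset = 3/8`.
* The covariate design is checked for full rank; conditioning dosages
  (stepwise, pseudo-phenotypes) may instead be dropped when collinear,
  with a warning, because collinearity there is expected rather than a
  user error.
* All randomness flows from explicit integer seeds; derived seeds are kept
  below 2³¹.

The trans-stage residualization is ordinary least squares on the declared
technical covariates. Published pipelines sometimes describe a linear mixed
model here without naming its random terms; with no way to recover that
structure, fixed-effect residualization — which coincides with the LMM when
the random-effect variance is zero — is the implemented and documented
behavior.

The per-SNP "product of p-values" summary is provided exactly as described
(`combine_snp_pvalues(method = "product")`) but is not a calibrated
p-value; Fisher's method is offered alongside and recommended when a
calibrated combination is wanted.

# Problem sizes in the checks

The test-suite and `scripts/acceptance.R` demonstrate, end to end: the
beta-approximation law on a 20-variant null window (n = 500, 1000
permutations) against the analytic $1-(1-p)^{20}$; FDR calibration on 500
null phenotypes; recovery of 3 planted independent signals (β = 0.5,
n = 1000) across 50 seeded runs; π1 recovery across mixtures (m = 1000);
trio model selection at n = 3000 (100 simulations per truth, δ = 10);
colocalization exactness by brute-force enumeration on ≤ 5-variant regions
and power on 40-variant regions (5% variance, n = 2000); mediated trans
recovery (paths 0.5 × 0.8, n = 2000); network exactness against BFS; and
byte-identical reruns of the bundled study under a fixed seed. These sizes
were chosen as the smallest at which each property is statistically
unambiguous.

# Known limitations

* Single-causal-variant colocalization only; no SuSiE-style multi-signal
  decomposition.
* Trios are three-node networks; latent confounders and >2-phenotype
  cascades are out of scope.
* The stepwise scan conditions on dosages, not haplotypes, and reports tag
  variants, not fine-mapped credible sets.
* π1 and q-value estimates inherit the usual instability of $\hat\pi_0$
  for small p-value sets; the bootstrap CI should always be reported with
  the point estimate.
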
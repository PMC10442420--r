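Package: omicqtl
Title: Multi-Omics QTL Mapping, Conditional Signals, Causal Trios and
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cis and trans quantitative trait locus (QTL) mapping for
    multi-layer molecular phenotypes (gene expression, circulating
    proteins, metabolites) with permutation-based beta-approximation
    multiple-testing correction and Storey q-values, forward-backward
    stepwise discovery of independent signals (allelic heterogeneity),
    pi1 estimation of shared genetic regulation, Gaussian Bayesian-network
    causal inference on SNP-phenotype-phenotype trios, approximate
    Bayes factor colocalization, and construction of typed SNP-phenotype
    regulatory networks.  A bundled synthetic multi-omics generator with
    planted regulatory architecture (Hardy-Weinberg genotypes with LD
    blocks, allelic heterogeneity, pleiotropy, mediated trans effects)
    makes every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
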
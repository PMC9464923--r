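Package: pleioverlap
Title: Cross-Trait Pleiotropy Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies polygenic overlap between two complex traits from
    GWAS summary statistics and discovers shared association signals.
    Implements harmonization of two summary-statistic sets, exclusion of
    long-range LD regions and genomic-control correction, stratified
    conditional Q-Q enrichment curves with random LD pruning, conditional
    and conjunctional false discovery rate (condFDR/conjFDR) estimation,
    FUMA-style locus definition with novelty and effect-direction
    classification, a bivariate Gaussian causal-mixture model of polygenic
    overlap (polygenicity, discoverability, Dice coefficient, genetic
    correlation, AIC model comparison), and approximate-Bayes-factor
    colocalization with molecular QTL signals. Includes a block-LD
    synthetic-GWAS generator with recorded causal truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
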
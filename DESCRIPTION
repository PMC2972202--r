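Package: rarestep
Title: Data-Driven Aggregation Tests for Rare Genetic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Score-based association tests for rare genetic variants that
    aggregate minor-allele dosages across a region using multiplicative
    weight models (continuous weight, effect direction, and inclusion
    indicator), including allele-frequency (inverse-variance) weighting,
    data-driven variant signing, variable minor-allele-frequency
    thresholds, functional-annotation groupings, and a greedy "step-up"
    search that selects the variant grouping maximising the score
    statistic.  Inference is by permutation of phenotypes with the entire
    data-adaptive procedure recomputed in each permutation.  Includes a
    combined multivariate and collapsing (CMC) logistic-regression
    comparator, a haplotype-pool simulator of case-control and
    quantitative-trait data with calibrated disease prevalence, and a
    driver for empirical type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
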
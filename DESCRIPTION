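Package: droughtmet
Title: Population-Scale Metabolome Analysis Under Drought Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, tested pipeline for population-level metabolomics
    under contrasting watering regimes: LC-MS feature-table filtering,
    redundancy collapse and normalization; drought-responsive metabolite calls
    by the intersection of OPLS-DA variable importance, paired-test FDR and
    fold change; structure- and kinship-corrected mixed-model association
    scans of metabolite and expression traits with suggestive thresholding,
    mQTL interval clustering, candidate-gene assignment and cis/trans eQTL
    classification; gene-metabolite network construction with
    permutation-calibrated hub-gene detection and pathway enrichment; and
    metabolome-based prediction of drought-tolerance indices with a ridge
    mixed model, cross-validation, bootstrap comparison and stepwise marker
    selection. A synthetic-data generator with recorded ground truth supports
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    boot,
    lme4,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    cluster,
    optparse
Config/testthat/edition: 3
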
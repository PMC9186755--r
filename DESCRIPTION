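Package: ioTNL
Title: Immunoediting-Optimized Tumor Neoantigen Load for Immunotherapy
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the immunoediting-optimized tumor neoantigen load
    (ioTNL), a genomic biomarker of response to immune checkpoint
    inhibition. From filtered somatic mutations with allele-specific copy
    number and tumor purity, the package estimates per-mutation cancer
    cell fractions, groups mutations into clone clusters, scores each
    clone's immunoediting stage as the ratio of neoantigen-bearing to
    non-silent mutations, and sums cancer-cell-fraction-weighted
    neoantigen loads over immune-elimination clones. Also provides
    high-confidence somatic variant filters using read-level evidence,
    cohort-level biomarker statistics (ROC/AUC, Youden dichotomization,
    editing-score cutoff optimization, Fisher exact, Mann-Whitney,
    Kaplan-Meier/log-rank, Cox hazard ratios), and synthetic-data
    generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
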
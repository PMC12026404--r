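Package: ibdatlas
Title: Multi-Omic Inflammation Severity Analysis for IBD Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cross-modality analysis of inflammation severity in
    inflammatory bowel disease (IBD) cohorts: normalization of histopathology
    disease-activity scores (modified Naini Cortina and modified Riley) to a
    common 0-1 scale, tissue- and date-matched inflammation-status labeling,
    serum-proteomic (Olink NPX) differential abundance and derivation of
    inflammatory protein severity signatures (IPSS), single-sample gene-set
    variation scoring (kernel-CDF rank random walk) for biopsy molecular
    inflammation scores (bMIS), cytokine signaling activity inference by ridge
    regression with permutation z-scores, attention-based multiple-instance
    regression of histologic activity from tile-feature bags, and
    over-representation / correlation evaluation utilities. Ships a synthetic
    multi-modal cohort generator driven by a shared latent severity so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
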
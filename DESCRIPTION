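Package: stressomics
Title: Multi-Omics Integration of Long-Lasting Acute-Stress Signatures in Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating small-RNA sequencing, RNA sequencing and
    tandem-mass-tag (TMT) proteomics of brain tissue after an acute stressor.
    Implements negative-binomial differential expression with median-of-ratios
    normalization, a two-cohort concordance filter for candidate microRNAs,
    TMT reporter-channel normalization and pooled-sample protein fold changes,
    anti-correlation integration of microRNA candidates against mRNA and
    protein targets predicted by multiple databases, hypergeometric
    over-representation analysis against GMT gene-set collections, and
    delta-delta-Ct qPCR relative quantification with one-sample fold-change
    tests. A synthetic-data generator with planted ground truth supports
    calibration and parameter-recovery testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
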
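Package: sigscreen
Title: Gene-Signature-Based Drug Screen Scoring and Tumor Immune Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring compounds in plate-based sequencing screens by
    their ability to down-regulate a chemokine gene signature (probe-level read
    counting with mismatch tolerance, stable-gene normalization, empirical-Bayes
    location/scale batch correction, per-plate DMSO fold changes and combined
    ranking), for identifying myeloid-derived suppressor cells (MDSCs) in
    single-cell RNA-seq by reference projection, for binned-control gene-module
    scoring and group comparisons, and for evaluating expression biomarkers of
    immunotherapy response and survival (z-scores, ROC/AUC, Kaplan-Meier,
    log-rank, automatic cutoff scans). Includes a synthetic-data module that
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    survival,
    glmnet,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
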
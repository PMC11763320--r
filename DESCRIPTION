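Package: cfMethDx
Title: Cell-Free DNA Quantification and Targeted Bisulfite Methylation
    Diagnostics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building and evaluating a non-invasive serum
    diagnostic from cell-free DNA: absolute quantification of cf-DNA by
    qPCR standard curve, targeted bisulfite amplicon sequencing with
    per-CpG methylation calling for a nine-gene panel, per-gene
    chi-square tests of differential methylation, and a composite
    elastic-net INDEX classifier benchmarked over repeated stratified
    hold-out splits. Includes a full synthetic-data generator (amplicon
    panels, cohorts, paired-end bisulfite reads, qPCR measurements) with
    known ground truth so every stage is testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    glmnet,
    jsonlite,
    rpart,
    randomForest,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
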
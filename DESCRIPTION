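Package: crossonc
Title: Cross-Species Comparative Oncogenomics of Copy Number, Expression,
    and Mutation Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative cancer genomics built around canine
    head-and-neck squamous cell carcinoma as a model of the human disease.
    Implements exact dynamic-programming change-point segmentation of aCGH
    log2-ratio profiles with FDR-controlled copy-number-abnormality calling,
    permutation-based scoring of gene-level CNA recurrence across tumors,
    integration of copy-number status with RNA-seq expression via a
    diploid-reference prediction-interval classifier, substitution-spectrum
    analysis with CpG/TpC context and virus-status group comparisons, and
    synteny-based projection of recurrently amplified regions between two
    genomes for driver-versus-passenger gene discrimination.  A synthetic
    data generator with known ground truth makes every stage testable
    without access to tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
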
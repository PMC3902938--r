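Package: translatomeRF
Title: Sequence Determinants of Stress-Dependent Translational Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline linking mRNA sequence features to stress-dependent
    translational regulation measured by polysome profiling. Calls per-gene
    translation states from log2 polysome:monosome intensity ratios with a
    moderated two-factor interaction test, builds a fixed-schema 77-feature
    vector per transcript (region composition, folding-energy proxy, CAI,
    fop, tAI, start-codon context, upstream ORFs, RNA-binding-protein motif
    sites, transcript levels), trains tuned class-weighted random forests
    with out-of-bag and cross-validated ROC evaluation and Gini importance,
    and tests gene-set co-association and term enrichment by hypergeometric
    statistics with Benjamini-Hochberg correction. Includes a synthetic
    transcriptome generator with planted regulons for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
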
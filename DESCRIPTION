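Package: labelsieve
Title: Label-Noise Screening for Alignment-Free Protein Sequence
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens labeled protein sequence collections for suspect
    class labels ("label noise"). Unaligned amino-acid sequences are
    mapped to fixed-length alignment-free representations (amino-acid
    composition, overlapping digram composition, z-scale auto-cross
    covariance, and summed skip-gram 3-gram embeddings), classified
    with one-vs-one support vector machines, Gaussian naive Bayes or
    random forests, and screened by a repeated cross-validation
    consistency analysis: per-sequence error rate, voting ratio and
    cumulative decision value against configurable thresholds produce
    a shortlist of sequences whose database labels deserve curator
    attention. Includes a seeded synthetic-data generator with
    injected label flips for end-to-end validation, dataset
    version comparison, and a pipeline/CLI front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
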
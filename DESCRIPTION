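Package: votesig
Title: Weighted-Voting Expression Signatures and Stem-Cell Transcriptome Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of age-associated tumor transcriptome
    signatures from log2 expression matrices: per-probe Welch tests with
    Storey positive-FDR q-values and Venn intersection filtering, a
    signal-to-noise weighted-voting classifier with leave-one-out
    cross-validation, panel-size scanning, prediction-strength scoring and a
    permutation null for the classification error, average-linkage distances
    of sample groups to embryonic-stem-cell reference profiles with standard
    errors, classical multidimensional scaling and principal-component
    projection onto a reference differentiation axis, and contingency-table
    comparisons of clinical covariates. Includes GCT/CLS readers and writers,
    a synthetic cohort generator with planted differential probe sets and a
    stemness gradient for end-to-end testing, and a single-config pipeline
    driver emitting delimited tables and a JSON run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
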
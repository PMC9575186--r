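Package: sigrobust
Title: Robustness Evaluation of Transcriptomic Subtype Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for systematically evaluating whether published
    gene-expression subtype signatures capture genuine tumor subtypes or
    confounding structure. Implements signature-restricted hierarchical
    clustering with Rand-index concordance, cross-cohort random-forest
    subtype classification with stratified cross-validation, size-matched
    random-signature and label-permutation null models summarized by the
    strictly standardized mean difference, single-sample gene-set
    enrichment scoring, non-negative least-squares cell-type
    deconvolution, Kaplan-Meier and pairwise log-rank survival comparison,
    and a synthetic multi-cohort expression generator with planted subtype
    signal, batch effects, normal-tissue contamination and
    subtype-dependent survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    pracma,
    randomForest,
    survival,
    withr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
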
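Package: itcatlearn
Title: Population Decoding and Learning Statistics for Paired
    Inferotemporal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous spike-count recordings from
    two inferotemporal subregions (TE and TEO) while a subject learns a
    morphed two-category visual task. Provides a synthetic-data generator
    emulating the morph-matrix stimulus design and region-dependent
    category-signal growth; per-neuron statistics (nested ANOVA with
    omega-squared effect size, ROC/AUC category preference with permutation
    significance, choice probability); population category, generalization,
    choice, and correct-versus-error decoding with an early-stopped linear
    read-out and paired shuffled controls; discriminability (d-prime) of
    single and pooled ensembles with a redundancy/complementarity taxonomy;
    representational dissimilarity over cross-identity image pairs; and
    cross-day inference (linear models with region-by-day interactions,
    bootstrap correlation-difference tests, permutation comparisons,
    false-discovery-rate correction, behavior-neural association, and
    psychometric fits).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
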
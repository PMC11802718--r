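Package: sudspanr
Title: Zero-Shot Extraction of Substance Use Disorder Severity Specifiers
    from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A workflow for extracting DSM-5 substance use disorder (SUD)
    diagnosis severity specifiers from unstructured clinical notes with a
    zero-shot text-generation model: per-category prompt construction,
    sliding-window chunking of long notes with a document stride, a pluggable
    greedy-decoding generation backend (with deterministic mock backends for
    testing), a four-stage post-processing cascade with lexicon filters and
    embedding-distance answer selection, a rule-based regular-expression
    baseline, strict and relaxed token-overlap span evaluation with
    macro-averaged reporting, and a seeded synthetic clinical-note generator
    emulating the documented statistical structure of the study corpus.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
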
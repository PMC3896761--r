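Package: trigtag
Title: Biomedical Event Trigger Recognition with Per-Type Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes biomedical event triggers (the words that signal molecular
    events such as gene expression or regulation) in pre-parsed scientific text.
    One linear-chain conditional random field is trained per event type over a
    rich linguistic feature set (token, orthographic, morphological, sentence,
    concept, dictionary and dependency-parse features, with window and
    conjunction context), and a greedy search optimizes each model's feature
    families, context mode, n-gram sizes, dependency-hop limits, vertex
    information and model order. Includes BioNLP A1 standoff and CoNLL-style
    readers and writers, case-insensitive dictionary matching, rule-based
    post-processing and exact-match micro-averaged evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
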
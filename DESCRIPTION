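Package: emrkg
Title: Clinical EMR Knowledge-Graph Construction with CRF-Based Entity
    Recognition and TF-IDF Knowledge Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for building disease-specific medical
    knowledge graphs from annotated clinical notes. Reads and writes BRAT
    standoff and CoNLL-style BIO corpora; augments training data with a
    dynamic entity replacement and masking (DERM) strategy; trains a
    toy-scale transformer + BiLSTM-CRF sequence labeler from scratch with
    exact Viterbi decoding and a log-space forward algorithm; normalizes
    variant entity surface forms against reference terminologies by
    character n-gram TF-IDF cosine similarity with automatic, review and
    reject tiers; assembles schema-validated (subject, relation, object)
    triples with bulk-import CSV and Cypher export plus multi-hop
    retrieval; and audits graph quality by stratified triple-accuracy
    sampling with insufficient-context exclusion. Ships a seeded
    synthetic-EMR generator so every pipeline stage is testable without
    private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
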
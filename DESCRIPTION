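Package: radner
Title: Radical-Augmented Bi-LSTM-CRF Named Entity Recognition for Chinese Adverse Drug Event Narratives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Character-level named entity recognition for Chinese adverse drug
    event (ADE) narratives. Tags Reason, Drug, and ADR entity spans with a
    bidirectional LSTM over character embeddings concatenated with Kangxi
    radical embeddings, decoded by a linear-chain conditional random field
    (Viterbi). Includes CoNLL-style BIO corpus input/output, length-limited
    sentence splitting, strict-boundary entity-level micro-F1 evaluation with
    multi-run aggregation, a man-machine comparison harness, and a seeded
    synthetic ADE-narrative generator so the full pipeline is testable without
    access to confidential pharmacovigilance corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
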
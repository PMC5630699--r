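Package: idiotope
Title: Idiotope Prediction Analysis for Immunoglobulin Heavy-Chain Variable Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline assessing the prerequisites for
    idiotope-driven T-B cell collaboration from immunoglobulin heavy-chain
    variable (IGHV) amino-acid repertoires. Generates CDR3-indexed 9-mer and
    15-mer fragments, predicts endosomal cathepsin S/L/B cleavage and
    fuzzy-logic peptide excision, predicts and Johnson-standardizes HLA
    binding affinities behind a pluggable predictor contract, classifies
    T cell-exposed motif (TCEM) rarity on a reverse-log2 frequency-class
    scale, and combines excision, affinity and rarity into a per-fragment
    idiotope score with per-position group statistics. Includes a seeded
    synthetic-repertoire generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    glmnet,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
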
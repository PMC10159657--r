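Package: tcrbind
Title: TCR-Peptide Binding Prediction with Random Forests on BLOSUM62 Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a T-cell receptor CDR3 beta chain recognises a
    given peptide (optionally in complex with a class-I HLA molecule) using a
    random-forest classifier over positional BLOSUM62 sequence encodings.
    Includes the surrounding pipeline: pair-table readers and validation,
    dataset curation (deduplication, conflict removal, subset construction,
    negative downsampling, unseen-peptide splits), model evaluation
    (ROC/AUC, accuracy, sensitivity, specificity, stratified reports),
    per-peptide false-positive attribution, binding-ratio titration,
    Levenshtein-similarity peptide clustering, and a synthetic-repertoire
    generator with a planted, exactly checkable binding rule for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    ranger,
    stats,
    utils
Suggests:
    class,
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
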
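Package: ademiner
Title: Mining Adverse Drug Event Relations from Case-Report Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sentence-level relation-extraction toolkit for
    pharmacovigilance text mining. Provides a standoff-annotation corpus
    model for case-report abstracts, dictionary-based named-entity
    recognition over drug and condition lexicons, automatic generation of
    negative (False) drug-condition pairs from unannotated co-occurrences,
    a shallow linguistic kernel (fore-between / between / between-after
    n-gram contexts plus positional local-context token features) with an
    exactly equivalent explicit feature map, linear support-vector-machine
    classification of candidate pairs, document-level cross-validation and
    learning-curve evaluation, and comparison of aggregated predictions
    against drug-label side-effect references to flag potentially novel
    adverse events. A synthetic-corpus generator with a ground-truth ledger
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
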
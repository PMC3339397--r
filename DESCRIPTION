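Package: eventmod
Title: Negation and Speculation Detection for Biomedical Event Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects NEGATION and SPECULATION modification of pre-identified
    biomedical event mentions.  Reads and writes BioNLP 2009 Shared Task
    standoff annotation (text plus .a1/.a2 files), represents Robust Minimal
    Recursion Semantics (RMRS) analyses and computes the qeq-outscoping scope
    algebra over them, extracts linguistically motivated negation and
    speculation features together with bag-of-words context-window features,
    combines evidence from multiple parser sources (fallback, union, and
    source-tagged union), trains one maximum-entropy classifier per subtask
    with class-prior fallback for unparsed sentences, and scores predictions
    at the modification level with recall, precision and F-score.  A
    synthetic-fixture generator produces desk-scale corpora exhibiting every
    phenomenon the features target, so the full pipeline can be exercised
    without the original shared-task corpus or any parser.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
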
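Package: dtifuse
Title: Multi-Channel Evidence Fusion for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate drug-target interactions (DTIs) by fusing three
    independent evidence channels: a degree-weighted path score over a drug-gene
    knowledge graph, a keyword-indicator score over literature search results,
    and a pluggable machine-learning binding predictor. A reasoning stage
    combines the channel scores into an explained final score under strict
    inter-agent format contracts, and an evaluation harness computes the
    standard binary-classifier metric suite (F1, precision, recall,
    specificity, AUROC, AUPRC). Includes seeded fixture generators for
    synthetic knowledge graphs, search-result sets, and predictor lookup
    tables so the whole pipeline runs deterministically offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
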
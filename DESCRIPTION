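Package: synergraph
Title: Multi-Omics Graph Neural Networks for Anticancer Drug-Combination
    Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts synergistic anticancer drug combinations from molecular
    graphs, extended-connectivity fingerprints, and cell-line gene- and
    protein-expression profiles. Provides graph attention, graph convolution
    and attentive-fingerprint encoders with a fusion network head for Loewe
    synergy-score regression and synergism classification; preprocessing
    filters for combination screens; cold-start (leave-combination-out,
    leave-drug-out, leave-cell-line-out) evaluation with the full metric
    suite; integrated-gradients feature attribution and attention-based
    atomic similarity analysis; and a seeded synthetic-fixture generator
    with planted substructure and protein-signature effects for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    e1071,
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
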
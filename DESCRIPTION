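Package: apmsfun
Title: Protein Function Prediction from AP-MS Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology categories for functionally
    uncharacterized (uPE1) proteins and their splice forms from
    affinity-purification mass-spectrometry (AP-MS) bait-prey tables.
    Purifications are scored under the matrix model with the Dice
    coefficient and a hypergeometric (Hart) scheme, the interaction
    threshold is calibrated against a gold-standard complex set by an
    F1 scan, GO annotations are filtered by evidence code, protein
    support and term level, functions are propagated on the weighted
    network with a cost-sensitive Hopfield classifier, and canonical
    versus splice-form interactome profiles are compared and binned by
    divergence. A synthetic-data module plants complexes, a GO DAG,
    proteoform pairs and masked proteins with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
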
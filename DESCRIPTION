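Package: gemcurate
Title: Ensemble-Driven Curation Targeting for Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates ensembles of alternative gap-filled genome-scale
    metabolic models consistent with growth phenotype data, simulates
    genome-wide single-gene essentiality across the ensemble, and applies
    unsupervised (k-means) and supervised (random forest) learning to rank
    network reactions by how much their structural uncertainty drives
    simulation uncertainty. The ranked reactions are prioritized curation
    targets for the model and for the reaction database used to build it.
    Includes a parsimonious-flux gap-filling linear program, a flux balance
    analysis core with gene-protein-reaction rule evaluation, subsampling
    saturation diagnostics, precision/recall evaluation against experimental
    essentiality screens, and pan-species aggregation with subsystem-level
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
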
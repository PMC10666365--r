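Package: melanocore
Title: Core Regulatory Network Extraction and Logic-Based Perturbation
    Screening for EMT Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to rank three-node feedback motifs in signed directed
    regulatory networks with a weighted multi-objective score, assemble a
    core regulatory network around the top-ranked motifs, translate the
    core into a fold-change-calibrated Boolean model with an ordinal
    epithelial-mesenchymal transition (EMT) phenotype readout, and screen
    in-silico perturbations for interventions that minimize (or maximize)
    the EMT level. Includes a seeded synthetic-data generator with planted
    feedback loops and ground-truth Boolean models, and a bundled
    melanoma-style fixture model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
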
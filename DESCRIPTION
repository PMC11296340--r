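Package: capop
Title: Population-Level Analyses for Longitudinal Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for population-level analysis of miniscope
    calcium-imaging experiments with repeated two-context training and probe
    sessions. Provides population-vector geometry (cosine-distance ratio of
    between- versus within-context distances with a label-permutation chance
    level), latent-space distribution distance (PCA projection, cross-validated
    kernel density estimates, symmetric Kullback-Leibler divergence on a grid),
    spectral-embedding trajectory visualization, cross-session population-vector
    similarity on registered cells, circular-shuffle normalized pairwise
    correlation matrices, eigenvalue-null ensemble extraction with
    cell-identity-shuffle activation scoring, synchronous calcium event
    detection, behavioral exclusion masks, and a synthetic-data generator that
    emulates the multi-day two-context design with known ground truth so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
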
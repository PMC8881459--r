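Package: slowsync
Title: Slow Oscillatory Coupling Between Cortical Electrophysiology and
    Resting-State fMRI Connectivity
Version: 0.1.0
Authors@R:
    person("Slowsync", "Developers", email = "maintainer@slowsync.dev",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how chemogenetic silencing of a
    cortical node reshapes brain-wide coupling: extraction of local field
    potentials and multi-unit activity from raw extracellular recordings,
    Kaiser-window spectrograms and band-power modulation indices, Welch
    magnitude-squared coherence, gamma-envelope infra-slow coherence,
    spike-field and LFP-LFP phase locking with surrogate significance,
    seed-based resting-state fMRI connectivity with k-means thalamic
    partitioning, and a von Mises spike-train simulation linking selective
    spike removal to low-frequency rhythm power. A synthetic-data module
    generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    matrixStats,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
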
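Package: piezoflux
Title: Interblade-Distance and Functional-Assay Quantification for PIEZO1
    MINFLUX Nanoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for 3D-MINFLUX/DNA-PAINT
    localization data of trimeric PIEZO1 channels: quality filtering of
    localizations (cfr/efo), trace grouping, trimming and refractive-index
    z-correction, trace centers-of-mass, DBSCAN merging of repeated
    DNA-PAINT detections into protomer sites, geometric identification of
    triple-labelled trimers and their interblade distances as a readout of
    channel flattening, and normality-gated two-group comparison of
    interblade-distance distributions. Also quantifies the accompanying
    functional assays (mechanical activation threshold, single-exponential
    inactivation time constant, Boltzmann pressure-response P50,
    single-channel amplitude and unitary conductance, calcium-imaging F/F0
    and sigmoid EC50) and per-residue ligand contact frequencies across
    docking-pose ensembles. Ships ground-truth-annotated synthetic data
    generators for every stage so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
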
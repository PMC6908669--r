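Package: reelmech
Title: Elastic-Network Dynamics, Nanomechanics and Sequence Conservation of Reelin Repeat Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the central BNR-EGF-BNR (BEB) repeat modules of
    reelin and proteins with the same fold. Builds anisotropic elastic network
    models from C-alpha coordinates and derives per-residue fluctuation (RMSF)
    profiles, slow-mode cross-correlation maps, and perturbation response
    scanning (PRS) maps with effectiveness/sensitivity profiles for
    sensor/effector mapping. Analyses conformational ensembles by rigid-body
    superposition and principal component analysis. Fits worm-like-chain (WLC)
    models to single-molecule force-extension curves, detects unfolding events,
    recovers contour-length increments, and computes disulfide-constrained
    maximum-extension bounds. Quantifies multiple-sequence-alignment
    conservation by per-column Shannon entropy and pairwise Hamming distance
    matrices with UPGMA cladograms. Includes seeded synthetic-data generators
    (bead structures with crosslinks and ion sites, mode-consistent Gaussian
    ensembles, piecewise-WLC force curves, conservation-controlled alignments)
    with ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
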
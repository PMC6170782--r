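Package: colonymix
Title: Agent-Based Simulation and Image Analysis of Clonal Mixing in
    Adhesive Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growing monolayers of rod-shaped bacteria as rigid
    capsules with tunable intercellular adhesion, modelled as a viscous drag
    opposing slippage transverse to the cell-cell contact normal.  Provides
    seeded in-silico experiments (microcolony morphology, two-domain lineage
    colonies, force propagation along cell chains), scalar colony readouts
    (interdomain contact ratio, circularity, colony radius), an image pipeline
    for two-channel colony micrographs (domain segmentation, interdomain
    boundary skeletons, normalized boundary length, Euclidean-distance-mapping
    fractal dimension), and a time-lapse pipeline (dense polynomial-expansion
    optical flow with simulation-based calibration, vorticity and RMS
    vorticity, lineage advection, line integral convolution rendering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
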
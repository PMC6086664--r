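Package: CytoQuant
Title: Quantification of Signaling Filopodia, Cytoneme-Mediated Morphogen
    Transport and Line-Scan Fluorescence Correlation Spectroscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of signaling filopodia
    (cytonemes) in fluorescence microscopy. Provides an automated
    detection pipeline (Gaussian smoothing, Hessian-eigenvalue
    objectness ridge enhancement, local adaptive thresholding,
    morphological cleanup, skeleton endpoint detection and livewire
    shortest-path tracing in 2D and 3D), per-cell morphometrics and
    percentile-based screen hit calling, a Monte-Carlo simulator of
    cytoneme-mediated morphogen dissemination through a growing cell
    lattice, and line-scan fluorescence correlation spectroscopy
    (lsFCS) analysis with multi-tau correlation and two-dimensional
    membrane diffusion model fitting. Synthetic ground-truth
    generators make every component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'lsfcs.R'
    'transport-simulator.R'
    'imaging-core.R'
    'livewire-tracing.R'
    'morphometrics.R'
    'pipeline.R'
    'cli.R'
    'io.R'
    'synthetic-data.R'
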
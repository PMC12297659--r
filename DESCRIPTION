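Package: axofit
Title: Rigid-Body Domain Fitting into Cryo-ET Density Maps and Axoneme
    Lattice Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A visual-proteomics toolkit for identifying proteins in
    subtomogram-averaged cryo-electron tomography density maps of the
    axoneme. Partitions predicted protein models into rigid units using
    the predicted aligned error (PAE) matrix, performs exhaustive
    rigid-body fitting of candidate domains into density with an
    FFT-accelerated locally normalized cross-correlation scan, and ranks
    candidates by global and size-binned local z-scores. Also provides
    the quantitative axoneme lattice analyses used alongside such atlases:
    filament-picking repeat bookkeeping, spiral-layout periodicity,
    axial overlap counting, bridge-density occupancy classification, and
    inter-microtubule edge-distance statistics. A synthetic-data module
    generates noisy density scenes with planted poses, block-structured
    PAE matrices, filament particle tables, and two-cylinder bridge
    phantoms so the entire pipeline is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust
Config/testthat/edition: 3
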
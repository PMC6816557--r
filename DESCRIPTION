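Package: matrixflock
Title: Two-Layer Nematic Flocking Model of Fibroblast-Driven Matrix Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of migrating fibroblasts coupled to an
    explicit extracellular-matrix layer. Cells are nematically aligning
    self-propelled agents whose heading combines persistent migratory noise,
    contact guidance from neighbouring cells and feedback from binned fiber
    orientations deposited, degraded and rearranged beneath their heads.
    Includes five matrix-topology metrics (long- and short-range alignment,
    high-density matrix, curvature, box-counting fractal dimension), a
    deterministic synthetic-pattern generator with known metric values,
    parameter-sweep and PCA summaries, persistence-based calibration of the
    noise and matrix-feedback parameters, and a two-phase matrix-remodeling
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    jsonlite,
    yaml,
    EBImage,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
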
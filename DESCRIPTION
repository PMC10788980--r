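Package: cellograph
Title: Semi-Supervised Graph Convolutional Scoring of Single-Cell Perturbation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, for every cell in a multi-condition single-cell
    RNA-seq experiment, how prototypical the cell is of its experimental
    condition. A k-nearest-neighbor graph over cells in PCA space is fed to
    a two-layer graph convolutional network trained semi-supervised on a
    small labeled subset (1-3% of cells per condition); the softmax output
    is a per-cell condition-probability matrix and the first-layer
    embedding supports clustering and visualization. Includes
    interpretable gene-weight ranking, latent-space k-means, multiclass
    Brier score and normalized mutual information evaluation, a
    negative-binomial synthetic-data generator with planted
    condition-specific marker programs, and readers/writers for MTX and
    h5ad containers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RANN,
    jsonlite,
    withr,
    rhdf5,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
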
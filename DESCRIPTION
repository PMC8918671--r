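Package: spottype
Title: Segmentation-Free Cell Typing for Single-Molecule Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rapid, segmentation-free cell typing of decoded single-molecule
    spatially resolved transcriptomics data (osmFISH, in situ sequencing and
    related assays). Per-gene local signal strength is estimated by a fast
    kernel density estimator that snaps molecules to a pixel grid and
    accumulates a pre-computed Gaussian mass patch truncated at two
    bandwidths. Each pixel is assigned the cell type whose reference
    expression signature correlates best with the pixel's gene expression
    vector; pixels below a total-expression threshold are classified as
    background. Includes relative cell-type abundance quantification over
    rectangular views, a subsection preview at full-run resolution for
    parameter optimization, a synthetic tissue simulator with ground truth,
    dataset down-/up-scaling utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    grDevices,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
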
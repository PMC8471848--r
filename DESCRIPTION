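Package: tmequant
Title: Quantification of Cell Motility, Morphology and Secretion in 3D
    Tumor Microenvironment Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 3D melanoma tri-cultures of macrophages,
    fibroblasts and tumor cells embedded in collagen. Reads single-particle
    tracking exports and computes per-track average speed and time-averaged
    mean squared displacement; measures single-cell shape indices
    (compactness, circularity, elongation) on segmented projection images;
    compares the motility of macrophages seeded close to versus far from
    tumor cells; preprocesses multiplex secretion plates (below-range
    imputation, log and z-score transforms, correlation, clustering, PCA)
    and classifies single-cell secretors; and provides a synthetic-data
    generator with known ground truth so every stage is verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    igraph,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
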
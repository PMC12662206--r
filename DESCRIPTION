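Package: OrganoidAxis
Title: Midline-Based Axis Quantification for Elongated Organoids
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the proximal-distal axis of elongated organoid
    sections imaged with targeted in situ transcriptomics. Extracts a
    morphological midline from binarized segmentation masks by least-cost
    routing along the ridge of the Euclidean distance transform, projects
    profiled cells onto the midline with a crowding-penalized distance,
    orients the axis with chondrogenic and fibroblast gene-set enrichment
    scores, classifies tissue polarization, and summarizes per-domain
    expression including a PCA centroid-distance comparison. A synthetic
    organoid generator (bent-capsule masks, scattered cells, gradient
    Poisson or negative binomial counts) provides ground truth for every
    stage. Mask morphometrics (moment-ellipse elongation classes and
    major-axis intensity profiles) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Software, Spatial, Transcriptomics, CellBiology, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
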
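Package: cdk2map
Title: Single-Cell CDK2 Activity Tracking and Cell-Cycle Protein Dynamics Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying proliferation-quiescence decisions in
    single cells from time-lapse fluorescence microscopy followed by endpoint
    immunofluorescence (IF). Implements nuclear segmentation with concavity
    ("deflection") bridging of touching nuclei, conservation-of-mass cell
    tracking with anaphase detection from H2B fluorescence halving,
    cytoplasmic-to-nuclear CDK2 sensor activity quantification,
    classification of post-mitotic fates (CDK2-increasing, CDK2-low,
    CDK2-emerging, prolonged quiescence), restriction-point detection,
    computational synchronization of traces to anaphase or to the
    restriction point, rigid jitter registration of fixed-cell IF images
    against the last live frame, snapshot cell-cycle phase gating from
    DNA content, EdU, phospho-Rb and phospho-histone-H3 markers, and
    construction of per-fate protein dynamics maps with moving averages and
    shared min-max normalization. A synthetic movie and IF generator with
    full ground truth supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
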
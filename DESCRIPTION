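Package: usquant
Title: Automated Quantification of Fat and Muscle in B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of 2-D B-mode musculoskeletal ultrasound
    scans of the abdomen and thigh. Implements the full measurement
    pipeline: grayscale correction, center-out region-of-interest
    extraction, edge-preserving bilateral filtering, template matching
    of anatomical interfaces with scale/contrast fallback variants,
    constraint-based anatomical ordering, morphological contour
    refinement, thickness and area measurement (rectangular and direct
    least-squares ellipse approximations), gray-level co-occurrence
    texture features, and Bland-Altman / mean-absolute-percentage-error
    agreement statistics against manual reference measurements. Ships a
    seeded speckle-phantom simulator with known layer-boundary ground
    truth so every stage is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jpeg,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, FeatureExtraction, Classification
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'agreement.R'
    'bmp.R'
    'detect.R'
    'dicom.R'
    'features.R'
    'geometry.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'synth.R'
    'usquant-package.R'
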
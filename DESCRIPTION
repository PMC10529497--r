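Package: boneTexture
Title: Texture-Based Bone Mineral Density Estimation from CT Hounsfield
    Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates areal bone mineral density (BMD) and bone mineral
    content (BMC) from the texture of trabecular bone in 2D CT slices
    measured in Hounsfield units. Implements rectangular region-of-interest
    isolation by HU thresholding, extraction of 45 texture features (5
    histogram moments plus 40 gray-level co-occurrence matrix statistics
    over 4 level counts and 2 orientations), z-score normalised linear
    regression against DXA reference targets, and correlation-based
    feature ranking with cross-target top-5 counting. A synthetic
    trabecular phantom generator (thresholded Gaussian random fields)
    provides fully reproducible cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    withr,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
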
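Package: osteoage
Title: Annotation-Free Cascaded Bone Age Assessment from Hand Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage, annotation-free bone age assessment for pediatric
    hand radiographs. Stage one discovers the two clinically critical bone
    regions (carpal bones and the metacarpus and phalanx area) with no
    manual bounding boxes: a convolutional network augmented with a
    convolutional block attention module (CBAM) drives gradient-weighted
    class activation (Grad-CAM) heat maps, and a cascaded crop-then-mask
    procedure walks the saliency peaks to localize the regions. Stage two
    predicts bone age in months with a two-branch convolutional regressor
    over the extracted regions, with mid-fusion feature exchange between
    branches and a learnable-weighted gender covariate. Includes a
    from-scratch attention and saliency engine with exact gradients, a
    synthetic radiograph generator with planted discriminative regions for
    desk-scale testing, RSNA-dialect label handling, and a command line
    interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
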
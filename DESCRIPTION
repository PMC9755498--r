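Package: aopseg
Title: Automatic Angle of Progression Measurement from Transperineal
    Ultrasound Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@aopseg.org",
           role = c("aut", "cre"))
Description: Automatic measurement of the fetal angle of progression (AoP)
    from transperineal ultrasound. Implements a dual-branch U-shaped
    segmentation network (shared encoder, full-resolution upper decoder and
    1/16-resolution lower decoder fused through attention gates and
    deformable convolution, trained with a collaborative Dice loss) for
    labelling the pubic symphysis and fetal head, direct least-squares
    ellipse fitting under the 4AC - B^2 = 1 conic constraint, three-key-point
    AoP geometry, the full segmentation and angle evaluation metric suite,
    and an ultrasound-like phantom generator with exact masks and analytic
    reference angles so every stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
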
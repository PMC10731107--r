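Package: spineqct
Title: Longitudinal Quantitative CT of Vertebral Bone and Paraspinal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal quantitative computed tomography (QCT) of the
    lumbar spine: phantom-based conversion of CT attenuation to volumetric bone
    mineral density, rigid registration of serial scans, construction and regional
    partition (superior/transverse/inferior) of the vertebral trabecular mask,
    paraspinal muscle cross-sectional area and attenuation-based density with a
    -50..150 HU analysis window, and cohort-level percent-change and monthly-rate
    statistics (paired and one-sample t-tests, bone-muscle regressions). Includes a
    seeded synthetic CT cohort generator with ground-truth sidecars for validating
    the full pipeline against known injected bone- and muscle-change trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
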
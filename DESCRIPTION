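Package: QCTscreen
Title: Opportunistic QCT Bone Density Screening and Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Opportunistic quantitative computed tomography (QCT) bone
    mineral density screening at the lumbar spine, from CT volume to
    case-control statistics. Generates synthetic perioperative lumbar CT
    phantoms with ground-truth label maps and pedicle-screw hardware,
    extracts trabecular regions of interest by posterior-element removal,
    metal exclusion at a Hounsfield-unit threshold and metric (millimetre)
    morphological erosion, converts attenuation to volumetric bone mineral
    density by asynchronous linear calibration, classifies patients by
    American College of Radiology density bands, and runs the matched
    case-control analysis stage: Levene-gated two-sample t-tests, Pearson
    chi-square on 2x2 tables, empirical ROC with Mann-Whitney AUC,
    Hanley-McNeil confidence intervals and the Youden-optimal operating
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
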
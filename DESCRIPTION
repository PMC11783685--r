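Package: poserom
Title: Markerless Joint Range-of-Motion Measurement and Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hip and knee joint range-of-motion (ROM) angles from 2D
    human-pose keypoints (shoulder, hip, knee, ankle in pixel coordinates)
    using law-of-cosines triangle geometry for sagittal movements and a
    right-triangle construction against the image vertical for hip rotations.
    Provides the companion manual-landmark reference-picture angles, the full
    test-retest reliability analysis (two-way random-effects intraclass
    correlation with F-based confidence intervals, standard error of
    measurement, minimal detectable change, Landis-Koch classification) and
    method-agreement analysis (Pearson correlation, Bland-Altman limits of
    agreement), plus a synthetic skeleton projector and study generator with
    known variance components so the whole pipeline can be exercised and
    validated without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
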
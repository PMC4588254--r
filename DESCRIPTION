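Package: pelvimetrix
Title: Landmark-Based Displacement Measurement for Unstable Pelvic Ring
    Fractures on Standardized Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies translational displacement and classifies rotational
    displacement of an injured hemipelvis from 2D landmark coordinates
    digitised on standardized inlet, outlet and anterior-posterior pelvic
    radiographs. Implements a pelvis-specific Cartesian frame with
    orthographic projection, femoral-head fiducial calibration from pixels
    to millimetres, difference-based displacement formulas with a
    configurable neutral band, inter-rater reliability statistics
    (two-way random-effects intraclass correlation with F-based confidence
    intervals, Fleiss and Cohen kappa with large-sample tests, Landis-Koch
    interpretation), and a virtual-radiograph simulator with known rigid
    ground truth for validating the measurement system in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
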
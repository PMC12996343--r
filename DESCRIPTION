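Package: pepsim
Title: Pepsin Activity Prediction and Gastric Digestion Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting human and porcine pepsin activity as a
    function of pH and temperature during in vitro gastric digestion.
    Ships the published log10-polynomial activity surfaces for both
    enzymes and the response-surface machinery that produces such
    models: ordinary least squares on polynomial term bases, ANOVA
    F tests, adjusted and PRESS-based predicted R-squared, studentized
    residual outlier flagging, and D-optimal design selection. Also
    provides the INFOGEST pepsin unit calculator, trapezoidal AUC
    comparison of digestion activity profiles, a gastric secretion and
    emptying mass-balance simulator (including a reduced pepsin-output
    scenario for older adults), a thermal-inactivation advisor, and
    seeded synthetic-data generators so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
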
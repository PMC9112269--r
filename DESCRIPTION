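Package: uwbanthro
Title: Noncontact Anthropometric Measurement from IR-UWB Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for noncontact anthropometric
    measurement with impulse-radio ultrawideband (IR-UWB) radar. Simulates
    multi-sensor radar recordings of a standing subject, removes static
    clutter with an exponential background filter, estimates standing height
    from a ceiling sensor by cell-averaging CFAR detection on the signal
    envelope, maps 5-second radar buffers from three sensors to RGB images,
    and regresses seven anthropometric parameters (height, weight, BMI and
    four body-composition percentages) with a three-branch late-fusion
    convolutional neural network, together with agreement statistics
    (RMSE, MAE, ICC(2,1), Pearson r squared) against reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
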
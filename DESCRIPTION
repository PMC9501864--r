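Package: shrapod
Title: Shrapnel Object Detection and Proximity Triage for Ultrasound Phantom Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting shrapnel and neurovascular landmarks (vein,
    artery, nerve) in ultrasound-like images and for scoring injury severity by
    shrapnel proximity. Includes a synthetic gelatin-thigh-phantom image
    generator with speckle texture and per-feature bounding-box annotations; a
    single-stage anchor-based object detector built on a SqueezeNet-style
    backbone with two YOLO-style output heads, trained by stochastic gradient
    descent with momentum and a quartic learning-rate warmup; IoU-gated
    detection evaluation (precision, recall, F1, average precision, mean IoU);
    and a triage metric that gates the minimum midpoint distance from shrapnel
    to the nearest neurovascular feature against multiples of the average
    artery diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
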
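Package: bleedwatch
Title: Intraoperative Bleeding Alerts from Surgical Video via Multi-Task
    Segmentation and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and anticipates intraoperative bleeding in endoscopic
    video at the frame level. A multi-task convolutional network with a
    shared U-Net encoder jointly segments surgical instruments and
    classifies frames as blood accumulation present or absent; the noisy
    per-frame bleeding confidence is stabilised with a causal Butterworth
    low-pass filter and escalated, parking-sensor style, into a bounded
    warning level whose threshold crossings become dichotomic alert
    events. Includes a seeded synthetic surgical-scene generator so the
    whole pipeline is trainable and testable without clinical data, and
    an evaluation suite covering event matching against human
    annotations, delta-time statistics with kernel density estimates,
    and multiple correspondence analysis of categorical outcome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    signal,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
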
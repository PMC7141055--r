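Package: camtrapeval
Title: Evaluation Protocols for Camera-Trap Species Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating species-classification
    workflows on camera-trap image collections: image catalogs backed by CSV
    manifests, a synthetic camera-trap world generator with location-specific
    procedural backgrounds, trained-location random splits and
    location-blocked k-fold splits that guard against background leakage,
    ratio-based rebalancing of imbalanced classes, seed-deterministic image
    augmentation, a desk-scale multinomial logistic reference classifier with
    ensemble voting, per-class precision/recall/F1 reporting, and
    recall-versus-training-set-size analysis with logarithmic trend fitting.
    Ships a transcription of a published per-species recall table from a
    Parks Canada camera-trap study for worked examples and calibration of the
    analysis conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
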
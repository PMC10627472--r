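Package: woundseg
Title: Adversarial Wound Segmentation and Morphometric Feature Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of skin wounds from RGB photographs with a
    conditional generative adversarial network (a U-Net generator trained
    against a patch-level discriminator using a compound adversarial plus
    L1 reconstruction loss), followed by morphological feature estimation:
    mask cleanup, connected-component labeling, region geometry (area,
    perimeter, axes), shape descriptors (eccentricity, circularity,
    rectangularity) and an approximate shape call used to suggest a
    dressing shape. Includes a seeded synthetic wound-scene generator so
    the full pipeline is testable without clinical images, standard
    overlap metrics (precision, recall, Dice, IoU), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
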
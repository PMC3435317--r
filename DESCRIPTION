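Package: woundkinetics
Title: Quantitative Morpho-Kinetic Analysis of Wound-Healing Time-Lapse
    Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated quantification of collective cell migration in
    bright-field (DIC) scratch wound-healing assays. Movies are segmented
    into cellular and wound regions by local texture variance, local motion
    is estimated per sub-cellular patch by normalized cross-correlation
    block matching, and per-frame velocity fields are summarised into
    velocity magnitude maps (mean speed versus distance from the wound edge
    over time). Healing is partitioned into three phases (pre-contact,
    contact-to-closure, post-closure); phase-by-distance descriptor vectors
    and rotation-invariant uniform local binary pattern (LBP) texture
    histograms feed leave-one-out SVM treatment classification with exact
    Wilcoxon rank-sum significance. A synthetic movie generator with full
    ground truth (prescribed velocity fields, wound geometry, cell tracks
    and morphology programs) supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
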
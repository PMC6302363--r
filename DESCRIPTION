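Package: tfdnaqa
Title: Quality Assessment of Docked Transcription Factor-DNA Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-based quality assessment of rigid-docked transcription
    factor-DNA complex models. Computes four structure-derived features per
    model (a distance-dependent atomic statistical potential, protein-DNA
    contact area from solvent accessible surface area, protein-DNA base
    hydrogen bonds, and bidentate hydrogen bonds), scores models with a
    Platt-calibrated support vector machine trained by hard-negative mining,
    and evaluates predictions with per-case outcome classification, Matthews
    correlation coefficient and accuracy. Includes an idealized B-DNA builder
    and rigid-body decoy generator so the full pipeline can be exercised
    without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
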
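Package: ksirt
Title: Kernel-Smoothed Item Response Theory for Shortening Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonparametric (Gaussian kernel smoothing) item response theory
    for polytomous rating-scale instruments. Estimates option and item
    characteristic curves from rank-based latent severity scores, derives
    item information, score density and standard-error curves, formalizes
    five operational criteria for classifying items as Very Good, Good or
    Weak, selects items for an abbreviated instrument, and links short-form
    summed scores to full-form summed scores through expected-score
    inversion and linear interpolation. Ships the 30-item PANSS scale
    definition and published reference tables as fixtures, plus a
    graded-response-model cohort simulator with configurable item
    pathologies for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
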
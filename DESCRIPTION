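Package: synergyscreen
Title: Checkerboard Combination Drug Screening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput combination drug
    screening in checkerboard (dose-matrix) format. Reads long-format
    plate tables, computes Z-prime plate quality control, normalizes raw
    optical densities to percent-of-vehicle viability, scores each dose
    matrix with ExcessHSA (excess over highest single agent) and Bliss
    excess, classifies interactions and ranks compounds across cell
    lines. Also provides Chou-Talalay median-effect fitting with per-well
    combination indices, four-parameter logistic IC50 fitting, tumor
    growth inhibition (TGI) scoring for xenograft arms, immuno-reactive
    score (IRS) computation, and a synthetic-data generator that builds
    checkerboard plates and xenograft growth curves with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
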
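Package: vigorlab
Title: Early-Vigor Phenotyping Pipeline for Two-Cultivar Rice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying early vigor in rice from hydroponic
    two-cultivar experiments. Fits the Farquhar-von Caemmerer-Berry model to
    A-Ci gas-exchange curves (Vcmax, Jmax) by exhaustive limitation-state
    segmentation, fits the non-rectangular hyperbola to A-Q light-response
    curves (Asat), computes blank-corrected hydroponic nitrogen and water
    uptake rates by mass balance, methylene-blue total and active root uptake
    areas, leaf nitrogen content and specific leaf weight, cultivar contrasts
    with Student's t-tests, seed-reserve regressions, 2^-ddCt relative
    expression, and a nitrogen-keyword filter for differential-expression
    tables. Includes a synthetic-experiment generator with known truth values
    for end-to-end validation and an orchestrated pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
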
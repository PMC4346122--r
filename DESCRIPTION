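Package: cbspredict
Title: Predicting Amyloid Status in Corticobasal Syndrome from Clinical
    Criteria and PET Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based classification of corticobasal syndrome (CBS) into
    frontal and temporoparietal clinical variants, quantitative FDG- and
    PIB-PET measures (pons-normalized SUVR, Logan graphical distribution
    volume ratios, control-referenced regional Z-scores, Z-difference
    classification, lateralization indices, amyloid-positivity
    thresholding), and diagnostic-performance evaluation of any binary
    predictor against amyloid PET status (sensitivity, specificity,
    predictive values with exact binomial confidence intervals, odds
    ratios, Fisher and chi-square tests, Cohen's kappa, concordance
    counting). Includes a synthetic-cohort generator with known
    ground-truth group structure and time-activity curves with known
    distribution volume ratios, so every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
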
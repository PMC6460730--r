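Package: longpred
Title: Encoding Repeatedly Measured Predictors for Fixed-Outcome Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and comparing prediction models whose predictor
    is a repeatedly measured variable (for example childhood BMI standard
    deviation scores) and whose outcome is fixed at a later age. Implements
    LMS-based z-score conversion with reference interpolation, the broken-stick
    piecewise-linear mixed model for regularising irregular longitudinal data
    onto a fixed knot grid, six encodings of the longitudinal predictor (all
    measurements, single measurement, mean/maximum summary, successive changes,
    conditional residualised measurements, and per-subject growth-curve
    parameters), collinearity-pruned logistic and linear prediction models, and
    performance assessment via adjusted Nagelkerke R-squared, adjusted
    R-squared, AUC, and the DeLong test for correlated AUCs. A seeded synthetic
    cohort generator emulating a birth-cohort growth study supports end-to-end
    evaluation of the methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
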
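Package: deconfound
Title: Confound-Aware Predictive Modelling for Biased Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating regression models from samples
    that are biased by confounds, i.e. variables that affect the features and
    whose sample association with the target differs from the population over
    which the model will be applied. Implements four strategies behind one
    train/predict interface (images only, confound-adjusted features, confounds
    as predictors, and density-ratio instance weighting), Gaussian-process
    regression with linear, ARD and bias kernels under homoscedastic and
    heteroscedastic Gaussian likelihoods, weighted balance diagnostics, a
    biased-sampling evaluation protocol with balanced and signed
    group-difference error metrics, a restricted (within-confound-level)
    permutation test, and synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
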
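Package: pvboot
Title: Partial Verification Bias Correction for Binary Diagnostic Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of sensitivity and specificity of a binary diagnostic
    test when disease status is verified by the gold standard for only a
    non-random subset of patients (partial verification, missing at random
    given the test result). Implements inverse probability bootstrap (IPB)
    resampling, which uses the verification propensity score to draw debiased
    synthetic samples of the verified cases, alongside complete case analysis,
    the Begg-Greenes Bayes-theorem correction, inverse probability weighting,
    and multiple imputation with Rubin pooling. Includes Wald, bootstrap
    normal, BCa, and Rubin confidence intervals, a multinomial simulator of
    partially verified diagnostic data, and a Monte-Carlo study runner that
    measures bias and standard error of each estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
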
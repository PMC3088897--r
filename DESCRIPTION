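Package: aafmc
Title: Alcohol-Attributable Fractions with Monte Carlo Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes alcohol-attributable fractions (AAFs) for chronic and
    infectious diseases from gamma-modelled consumption distributions among
    current drinkers and continuous (fractional-polynomial) relative-risk
    curves, and estimates their 95% confidence intervals by Monte Carlo
    propagation of uncertainty in all lowest-level input parameters
    (relative-risk coefficients, adult per-capita consumption, abstainer and
    former-drinker prevalences, and the gamma shape parameter). Includes
    partial AAFs by consumption band, categorical (old-method) AAFs,
    one-at-a-time variance decomposition, batch-based convergence
    diagnostics, and a synthetic fixture generator for self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
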
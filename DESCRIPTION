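Package: nlmedrc
Title: Nonlinear Mixed-Effects Dose-Response Association Tests for
    High-Throughput Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits four-parameter logistic dose-response curves to
    high-throughput drug-screen viability data, either per cell line by
    least squares or jointly across a cell-line panel with a nonlinear
    mixed-effects (NLME) model carrying a Gaussian random effect on the
    curve midpoint (the log10 IC50).  Provides three association tests
    between drug response and a per-cell-line feature: the traditional
    t-test/correlation on individually fitted IC50s, the analogous test
    on NLME conditional IC50s, and an omnibus likelihood-ratio test that
    compares pooled versus group-stratified NLME fits with significance
    assessed by label permutation (with early stopping and adaptive
    escalation of the permutation count).  Includes a screen simulator
    and a harness for estimating type-I error and power of the three
    tests under configurable scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
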
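Package: strataDP
Title: Optimum Stratum Boundaries and Sample Sizes by Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines optimum stratum boundaries (OSB) and optimum stratum
    sample sizes for a study variable in stratified survey designs using
    readily available auxiliary variables. The stratification problem is cast
    as a separable mathematical programming problem over stratum widths and
    solved exactly on a grid by dynamic programming, with closed-form
    truncated-moment objectives for three-parameter Weibull and Gamma
    auxiliary distributions and a homoscedastic normal regression error.
    Includes Neyman allocation with unit and capacity bounds, strata-count
    profiling, classical cum-sqrt(f) and geometric baseline stratifiers,
    maximum-likelihood fitting of three-parameter skewed distributions with
    Kolmogorov-Smirnov checks, and a synthetic-population generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
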
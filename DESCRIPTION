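Package: mixamount
Title: Mixture-Amount Experimental Design and Response-Surface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing mixture-amount experiments in
    which the blend composition of several components and the total amount
    applied vary jointly. Provides crossed Scheffe polynomial bases, D-optimal
    point-exchange design construction with lack-of-fit, replicate and center
    augmentation and block assignment, no-intercept least-squares fitting with
    mixture-convention ANOVA (lack-of-fit / pure-error partition), sequential
    model-order selection and backward elimination, regression adequacy
    diagnostics (studentized residuals, Cook's distance, DFFITS, DFBETAS,
    Box-Cox transformation profiles, prediction precision), response-surface
    prediction and slice grids, and a seeded synthetic-study generator
    emulating a five-component phenolic diet experiment on tephritid fruit-fly
    development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
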
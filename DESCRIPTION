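Package: dmproj
Title: District-Level Diabetes Burden Projection Under Intervention Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to project diabetes prevalence, cases, deaths and
    complications for a set of districts from a cross-sectional prevalence
    regression on risk-factor prevalences and non-communicable-disease
    programme coverages. Implements bivariate screening, backward elimination
    with a confounder-retention rule, regression assumption checks, linear and
    random-normal dynamization of predictors, three intervention scenarios,
    case-fatality and complication burden accounting, MAPE forecast
    validation, and a seeded synthetic district panel generator so the whole
    pipeline is testable without access to the underlying survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    lmtest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tidyr,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
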
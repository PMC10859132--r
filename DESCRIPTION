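Package: simtrace
Title: Checkable, Recreatable Monte Carlo Simulation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An engine and checking toolkit for Monte Carlo simulation
    studies of statistical methods, built around a worked example that
    compares complete-case analysis with multiple imputation for a
    missing confounder in logistic regression. Provides state-reproducible
    data generation under MCAR, MAR and MNAR missingness mechanisms,
    guarded analysis execution that captures method failures, Firth
    penalized logistic regression as a backup under separation, Rubin's
    rules pooling with Barnard-Rubin degrees of freedom, performance
    measures (bias, empirical and model-based standard error, coverage,
    rejection and failure rates) with Monte Carlo standard errors, and
    diagnostic instruments: standard-error-versus-estimate scatter data,
    outlier flagging, zip plots and Monte Carlo compatibility checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
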
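Package: micromacro
Title: Micro-Macro Multilevel Regression with Latent-Mean Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts a quantitative group-level outcome (such as a yearly
    staff turnover rate) from individual-level and group-level covariates.
    Observed group means of individual-level predictors are replaced by
    latent-variable-adjusted means (best linear predictors of the latent
    group scores), removing the aggregation bias of naive group-mean
    regression. Supports mixed quantitative and qualitative predictors via
    dummy coding, heteroscedasticity-consistent standard errors,
    hierarchical clustering of mixed-type variables with bootstrap
    stability, exhaustive best-subset selection by AIC, a simulation-based
    test of zero between-group variance, and a Monte-Carlo harness for
    bias and coverage evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
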
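Package: crctcompare
Title: Comparative Estimation for Cluster Randomised Controlled Trials
Version: 0.1.0
Authors@R: person("CRCT", "Methods", email = "crct@example.org", role = c("aut", "cre"))
Description: Fits the four families of individual-level models routinely
    compared for cluster randomised controlled trials: random-intercept
    generalized linear mixed models (ML/REML for continuous outcomes,
    adaptive Gauss-Hermite quadrature for binary outcomes), first-order
    generalized estimating equations with independence or exchangeable
    working correlation, second-order GEE via the three-estimating-equation
    formulation with a Fisher-z correlation link, and the quadratic
    inference function estimator with its chi-square goodness-of-fit
    objective. Includes intracluster correlation coefficient estimators
    (model-based and one-way ANOVA), Satterthwaite degrees-of-freedom and
    Fay-Graubard small-sample corrections, a synthetic trial generator
    emulating primary-care cluster trials, and a simulation pipeline that
    computes operating characteristics (bias, coverage, type-I error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    numDeriv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
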
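Package: bivintent
Title: Joint Bayesian Bivariate Gaussian Regression of Preventive-Behaviour Intentions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of two bounded 0-100 behavioural-intention scores
    (COVID-19 vaccination and contact-tracing-app download) with a Bayesian
    bivariate Gaussian distributional regression in which location, scale and
    correlation parameters all depend on covariates, the correlation through
    the rhogit link rho/sqrt(1-rho^2). Includes maximum-likelihood
    initialisation, blockwise adaptive Metropolis sampling, DIC-based forward
    covariate selection and thin-plate spline age effects; single-factor
    score extraction with tercile and zero-inflated categorical codings;
    a mixed-effects cumulative logistic model of protection motivation with
    adaptive Gauss-Hermite quadrature; nonparametric descriptive tables; and
    a synthetic survey-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
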
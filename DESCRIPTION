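Package: riskclass
Title: Latent Class Models for Survey Health Indicators and
    Quality-of-Life Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of population health surveys in the style of
    the Behavioral Risk Factor Surveillance System (BRFSS). Stage one fits
    design-weighted latent class (binary Bernoulli-mixture) models to
    dichotomous health indicators within four domains (risky behaviors,
    health conditions, health care access, preventive services) by
    expectation-maximization, selects the number of classes by the Bayesian
    information criterion, and orders classes by risk. Stage two regresses
    dichotomized health-related quality-of-life outcomes (frequent physical
    and mental distress, 14 or more unhealthy days in the past 30) on the
    latent classes with weighted logistic regression and robust sandwich
    variances. Includes a seeded synthetic survey generator with known
    ground-truth latent structure, structural missingness for sex- and
    age-gated screening items, and item nonresponse, so the whole pipeline
    is testable without confidential microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
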
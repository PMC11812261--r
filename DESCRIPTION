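Package: twinace
Title: Longitudinal Twin ACE Cholesky Models for Child Eating Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-group (monozygotic/dizygotic) longitudinal twin analyses of
    emotional overeating in children: scoring of the Child Eating Behaviour
    Questionnaire emotional-overeating subscale, covariate residualization,
    double-entry twin correlations with Fisher confidence intervals,
    trivariate Cholesky ACE models estimated by full-information maximum
    likelihood with saturated baselines and likelihood-ratio model
    comparison, profile-likelihood and bootstrap confidence intervals, and a
    synthetic twin-cohort generator emulating the Gemini birth cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
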
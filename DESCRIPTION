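Package: mediscreen
Title: Causal Mediation Screening of Blood Biomarkers with Debiased
    Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-parametric one-step estimation of total, natural direct,
    and natural indirect effects of a binary exposure on many continuous
    blood traits through an activity mediator. Nuisance functions
    (propensities, outcome regressions, pseudo-outcome regressions) are fit
    with a cross-validated stacked ensemble (Super Learner) over a pluggable
    learner library, with cross-fitting and Wald inference from the
    efficient influence function. Includes a synthetic-cohort generator with
    analytically known effects, trait transformations (composite
    insulin-resistance indices, winsorisation, complete-case and
    special-code filtering, repeated-measurement averaging), multi-trait
    screening with Benjamini-Hochberg false discovery rate control,
    z-score concordance analysis, matched subgroup comparison, and a
    command-line interface.
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
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
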
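# mediscreen

Causal mediation screening of blood biomarkers with debiased machine
learning.

## What it does, and for whom

Case/control comparisons of blood traits are confounded whenever the disease
itself restricts physical activity: a biomarker may differ because of the
disease, or merely because cases move less. `mediscreen` is for
epidemiologists and biostatisticians screening many continuous traits
(clinical chemistry, metabolomics, proteomics) in biobank-style cohorts who
need that distinction made explicit. For confounders `W` (age, sex), binary
exposure `A`, a non-negative activity mediator `M` and each trait `Y`, the
average total effect decomposes by the mediation formula

```
E[Y(1) - Y(0)]  =  {E[Y(1, M(0))] - E[Y(0, M(0))]}  +  {E[Y(1, M(1))] - E[Y(1, M(0))]}
      TE        =                NDE                 +                NIE
```

into a natural direct effect (all pathways except activity) and a natural
indirect effect (the activity channel only). Each counterfactual mean
`psi(a, a') = E[Y(a, M(a'))]` is estimated by a semi-parametric one-step
estimator: Super Learner fits of the nuisance functions — exposure
propensity `g(a|W)`, outcome regression `mu(a, M, W)`, pseudo-outcome
regression `eta(a'; a, W)`, and a mediator-conditional propensity
`e(a|M, W)` that re-expresses the mediator density ratio through Bayes'
rule — followed by a bias correction from the efficient influence function,
with cross-fitting, propensity truncation and Wald confidence intervals.
Around the estimators sits the full screening workflow: composite
insulin-resistance indices (TyG, TG-to-HDL-C), winsorization,
complete-case and questionnaire non-response filtering,
Benjamini–Hochberg FDR control per multiplicity family, z-score concordance
between analyses, matched case-subgroup comparisons with disjoint controls,
and a synthetic-cohort generator with analytically known effects so every
stage is testable without access-controlled data.

## Worked example

Simulate a small cohort with three traits whose true effects are purely
direct (two elevated in cases, one lowered), then screen it:

```r
library(mediscreen)
library(dplyr)

beta <- data.frame(trait = c("crp", "triglycerides", "urea"),
                   intercept = c(2, 1.5, 5.4), A = c(0.45, 0.3, -0.25),
                   M = 0, age = 0.01, sex = 0.1, sigma = 1)
sem <- sem_config(n_cases = 400, n_controls = 3600, beta = beta, seed = 42)
sim <- generate_cohort(sem)
sim$truth
#>   trait            TE   NDE   NIE
#> 1 crp            0.45  0.45     0
#> 2 triglycerides  0.3   0.3      0
#> 3 urea          -0.25 -0.25     0

res <- run_screen(sim$cohort, c("crp", "triglycerides", "urea"),
                  mediators = "activity", strata = "combined",
                  estimands = c("TE", "NDE", "NIE"),
                  config = screen_config(library = fast_learner_library(),
                                         K = 5, seed = 42))
res %>% select(trait, estimand, estimate, se, z, p_adj, significant)
#>   trait         estimand estimate     se      z    p_adj significant
#> 1 crp           TE        0.449   0.0557  8.07  2.00e-15 TRUE
#> 2 crp           NDE       0.423   0.0633  6.68  6.99e-11 TRUE
#> 3 crp           NIE       0.0300  0.0289  1.04  8.96e- 1 FALSE
#> 4 triglycerides TE        0.257   0.0581  4.43  1.43e- 5 TRUE
#> 5 triglycerides NDE       0.282   0.0674  4.18  4.40e- 5 TRUE
#> 6 triglycerides NIE       0.00442 0.0335  0.132 9.16e- 1 FALSE
#> 7 urea          TE       -0.173   0.0606 -2.86  4.20e- 3 TRUE
#> 8 urea          NDE      -0.167   0.0691 -2.41  1.58e- 2 TRUE
#> 9 urea          NIE       0.00406 0.0386  0.105 9.16e- 1 FALSE
```

Each row is one (trait, estimand) cell: the point estimate in trait units,
its influence-function standard error, z-score, BH-adjusted p-value within
the (stratum × estimand × mediator) family, and the FDR < 0.05 flag. The
screen recovers the generative truths — all three direct and total effects
are significant with the right signs and magnitudes, while no indirect
effect is (their truth is zero; `estimate` stays within noise of 0).

Summary statistics work the same way from printed values, e.g. Welch's
unequal-variance comparison of case vs control BMI in a male cohort:

```r
welch_t(27.96, 4.62, 386, 26.80, 3.58, 55572)
#>       t    df          p
#> 1  4.92  388. 0.00000126
```

A command-line interface wraps the same functions
(`inst/cli/mediscreen simulate|screen|report`); a commented run-config
example lives at `inst/examples/run-config.yaml`, and every output
directory receives a JSON manifest (config echo, seeds, conventions)
sufficient to re-run bit-identically.

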
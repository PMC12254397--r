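---
title: "Screening blood biomarkers with one-step causal mediation estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening blood biomarkers with one-step causal mediation estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediscreen)
library(dplyr)
```

## The problem

Diseases that restrict physical activity confound any blood-biomarker
comparison between cases and controls: a trait may differ because of the
disease itself, or merely because cases move less. `mediscreen` separates
these channels for every trait in a biobank-scale screen. With `W` the
baseline confounders (age and sex), `A` a binary case/control exposure, `M`
a non-negative activity mediator (e.g. minutes of walking per day) and
`Y` a continuous blood trait, the average total effect decomposes by the
mediation formula into a natural direct effect and a natural indirect effect:

$$
\underbrace{E[Y(1) - Y(0)]}_{TE}
 = \underbrace{E[Y(1, M(0))] - E[Y(0, M(0))]}_{NDE}
 + \underbrace{E[Y(1, M(1))] - E[Y(1, M(0))]}_{NIE}.
$$

`Y(a, M(a'))` is the outcome when the exposure is set to `a` while the
mediator takes the value it would naturally have under exposure `a'`. The
NDE captures every path from exposure to trait except the one through
activity; the NIE captures only the activity channel. A biomarker whose
effect is mostly direct cannot be explained away by restricted activity.

Identification requires the usual assumptions: consistency/no interference,
joint exchangeability of exposure and mediator given `W`, positivity of both
exposure and mediator assignment, and cross-world counterfactual
independence `Y(a, m) ⊥ M(a') | W`. The last is not empirically verifiable;
estimates on observational cohorts should be read as associational natural
effects under that assumption.

## Estimators

Every counterfactual mean `ψ(a, a') = E[Y(a, M(a'))]` is estimated by a
one-step efficient estimator: an initial machine-learning fit of the
nuisance functions followed by a bias correction equal to the empirical mean
of the estimated efficient influence function (EIF). The uncentred EIF used
here is

$$
D_i = \frac{1\{A_i = a\}}{g(a \mid W_i)}\, r(M_i, W_i)\,
      (Y_i - \mu(a, M_i, W_i))
    + \frac{1\{A_i = a'\}}{g(a' \mid W_i)}
      (\mu(a, M_i, W_i) - \eta(a'; a, W_i))
    + \eta(a'; a, W_i),
$$

with nuisance functions

* `g(a | w)` — exposure propensity,
* `μ(a, m, w) = E[Y | A = a, M = m, W = w]` — outcome regression, fit per
  exposure arm,
* `η(a'; a, w) = E[μ(a, M, W) | A = a', W = w]` — pseudo-outcome
  regression, fit by regressing predicted `μ(a, M_i, W_i)` on `W` among
  subjects with `A = a'`,
* `r(m, w)` — the mediator density ratio
  `p(m | a', w) / p(m | a, w)`, re-expressed through the
  mediator-conditional propensity `e(a | m, w) = P(A = a | M = m, W = w)`
  by Bayes' rule as `r = [e(a'|m,w) / e(a|m,w)] · [g(a|w) / g(a'|w)]`.
  This avoids estimating conditional densities of a continuous mediator
  entirely; `r ≡ 1` when `a = a'`, where the estimator reduces to standard
  augmented inverse probability weighting (AIPW).

`estimate_nde_nie()` differences the three `ψ` estimates that share one set
of nuisance fits, so `NDE + NIE = TE` holds to machine precision row by row.
The total effect reported in the main screen comes instead from
`estimate_te_aipw()` on the larger complete-case sample that does not
require the mediator; the two total effects agree up to sampling noise on
well-specified data, and decomposition fractions always use the
shared-nuisance version so the identity is exact where fractions are shown.

Inference is Wald-type from the influence values: `se = sd(D) / √n`,
`z = estimate / se`, two-sided normal p-values. The normal reference (not
t) matches the asymptotic theory at biobank sample sizes.

### Super Learner

All nuisances are fit by a cross-validated stacked ensemble
(`fit_superlearner()`). Base learners implement a common fit/predict
contract; the default library covers the archetypes usual in this
literature: an adaptive smoothing-spline regression (via `mgcv::gam`), the
LASSO (`glmnet`, internal tenfold lambda selection), a GLM with all two-way
interactions, and gradient boosting (`xgboost` with implementation
defaults). The meta-learner minimises the cross-validated squared-error
risk over the probability simplex, solved *exactly* by active-set
enumeration — feasible because libraries are small — so the stacked
ensemble provably never has higher cross-validated risk than its best
member. For binary nuisances the learners return probabilities and the
meta-step minimises the squared-error (Brier) risk on held-out
probabilities, so the recorded per-learner `cv_risks` are on the same scale
the weights optimise. A learner that fails on any training split is dropped
with a warning rather than aborting a screen of thousands of traits; with a
single learner the weight is forced to one (the "no Super Learner" baseline
used for sensitivity analysis reduces the library to the penalised GLM
alone).

### Cross-fitting, truncation, clipping

Cross-fitting is on by default: each subject's nuisance predictions come
from fits excluding that subject's fold, the standard device that preserves
valid Wald inference when the library contains adaptive learners. The fold
scheme is shared between cross-fitting and the Super Learner (`K = 10` by
default; a 20-fold stratified variant mirrors the replication-cohort
configuration and is available through `make_folds(stratify_labels = )` and
`stratify_cv`). Estimated propensities are truncated to
`[δ, 1 − δ]` with `δ = 0.025` by default (configurable, recorded in the
output manifest; `δ = 0` disables truncation for exact nonparametric
checks). Binary-family ensemble predictions are additionally clipped to
`[0.001, 0.999]` so density-ratio terms stay finite.

## The synthetic cohort generator

`generate_cohort()` draws cohorts from an explicit linear structural
equation model — logistic exposure confounded by age and sex, Gaussian
mediator shifted by exposure and floored at zero (activity durations are
non-negative), Gaussian traits loading on exposure, mediator and
confounders — and returns the analytically known per-trait truths
`NDE = β_A`, `NIE = β_M α_A`, `TE = β_A + β_M α_A`
(`closed_form_effects()`). Defaults emulate a large biobank case/control
design: ~1455 expected cases against ~131,303 controls, recruitment ages
uniform on 40–69, 73% female, a mediator near 55 min/day in controls and
44 in cases, twenty traits whose standardised total effects span 0.2–0.5,
a 55% case subgroup flag, 5%/2% missingness on mediator/traits, and 1%
special mediator response codes (sentinels −1/−3, the questionnaire
non-response analogues).

What the generator deliberately does **not** emulate: measurement heaping
of self-reported durations (minutes cluster at multiples of 5/10 in real
questionnaires), assay batch effects, non-Gaussian trait tails beyond what
winsorization addresses, informative (MNAR) missingness, and longitudinal
structure beyond a simple repeated-measurement averaging mode. Passing
tests on these cohorts therefore demonstrates the estimation machinery and
its calibration, not robustness to every artefact of real questionnaire
data.

Two numerical points deserve note:

* **Flooring vs closed forms.** The non-negativity floor makes the system
  mildly nonlinear, while the closed-form truths ignore the floor.
  Simulation studies in this package therefore use coefficient regimes
  where the floor binds with negligible probability (well under 0.1% of
  draws; the default control mean of ~55 min/day with SD 20 floors ~0.3%,
  acceptable for screening demonstrations but not for calibration studies).
  `closed_form_effects(method = "monte_carlo")` honours the floor when an
  exact truth under flooring is needed.
* **Special codes.** Non-response sentinels are negative by construction
  and therefore provably disjoint from valid mediator values; the response
  filter is code-set-driven (`mediator_response_filter()`), never
  hard-coded.

## Trait transformations

Composite insulin-resistance indices follow their standard definitions:
`TyG = ln(TG[mg/dL] × glucose[mg/dL] / 2)` (`compute_tyg()`, with fixed
conversion constants 88.57 and 18.018 from mmol/L and a switch to skip
conversion, since assay units differ across biobanks and either reading of
the original computation is possible) and the TG-to-HDL-C ratio. Composites
are missing whenever any component is missing, and with repeated
measurements the composite is computed per contemporaneous component pair
first, then averaged per subject (`average_repeated_measurements()`) — the
order matters and is tested.

Winsorization clips at inverse-ECDF (type 1) quantiles. The choice is
deliberate: interpolated quantile conventions make winsorization *not*
idempotent (re-clipping moves the bound again, by up to ~1e−3 on typical
data), while the inverse-ECDF bound is itself the corresponding quantile of
the clipped data, making the operation an exact fixed point. The convention
is recorded in every output manifest. Cohen's d uses the pooled-SD form.

## The screening workflow

`run_screen()` iterates strata × mediators × traits. Within a sex stratum,
sex leaves the confounder set (it is constant); the combined analysis keeps
it. Total effects use complete cases on (confounders, exposure, trait)
only; direct/indirect effects additionally require the mediator and remove
special-code responses first. Benjamini–Hochberg adjustment
(`bh_adjust()`, delegating to `stats::p.adjust` with missing values
excluded from the family and reinserted) is applied within each
(stratum × estimand × mediator) family by default — the most conservative
family structure consistent with per-analysis significance reporting — with
a global mode available. A cell that cannot be estimated yields a row of
missing estimates and a warning, never a silently dropped trait.

Downstream summaries mirror the standard presentation of such screens:
`zscore_concordance()` pairs per-trait z-scores across two analyses
(female vs male, cohort vs cohort) with a Pearson correlation and a
both/only/neither significance classification; `effect_fractions()` reports
NDE and NIE as shares of the shared-nuisance total effect (undefined below
a |TE| floor of 1e−8 outcome units, where ratios are meaningless);
`pem_split_comparison()` implements the matched subgroup design — the
larger case subgroup subsampled without replacement to the smaller's size,
controls partitioned into two disjoint equal halves, total effects screened
per arm; `stringency_sensitivity()` compares z-scores across cohort
variants that differ in case/control definition stringency.

## Calibration studies and problem sizes

The package's validation suite (and `scripts/acceptance.R`) runs these
studies, chosen to complete comfortably on one CPU:

* **Exact checks.** The decomposition identity `NDE + NIE = ψ(1,1) − ψ(0,0)`
  to 1e−12 on an n = 2,000 cohort; on all-binary data with saturated
  (empirical-frequency) nuisances, truncation disabled, the one-step
  estimates equal exhaustive g-computation sums to 1e−10 at n = 500 — at
  the nonparametric MLE the EIF correction averages to zero, so any
  discrepancy would expose an implementation fault.
* **Parameter recovery.** 200 replicates of an n = 5,000 linear-SEM cohort
  with a 20% case fraction, mediator mean 100 and SD 15 (floor probability
  < 1e−8, so the generating system is exactly linear), single-GLM nuisance
  library (correctly specified), K = 5 cross-fitting: NDE and NIE biases
  within three Monte-Carlo standard errors of zero and 95% Wald coverage
  for both inside [92%, 98%]. The 20% case fraction keeps propensities
  well inside the truncation bounds; with much rarer exposures (10% and
  below at this n) the inverse-propensity weights grow heavy-tailed and
  Wald coverage erodes by a few points before asymptotics recover it — a
  finite-sample property of one-step estimators worth remembering when
  case counts are small, not an implementation defect (verified by
  plugging analytically true nuisances into the same estimator).
* **Null calibration.** 20 replicates of a 50-trait screen with the
  exposure–mediator path set to zero: the fraction of FDR-significant NIEs
  stays consistent with the nominal 5%. Because all traits in a replicate
  share one cohort draw, their tests are strongly dependent and false
  discoveries arrive family-wide; the binomial tolerance is therefore
  computed with the replicate as the unit.
* **Property suites.** BH against a brute-force step-up implementation on
  1,000 random vectors; Super Learner simplex and risk-domination
  invariants on every fit; winsorization idempotence/monotonicity and
  composite-index unit identities.

## Known limitations

Single mediator per estimand (multiple mediators are screened separately,
not jointly); MCAR missingness only in the generator; no interventional
(randomised) mediation estimands or survival outcomes; no
targeted-maximum-likelihood variant; concordance requires at least three
shared traits; the exact simplex meta-learner enumerates subsets and is
limited to 14 learners (far above practical library sizes). Estimates on
rare-exposure cohorts inherit the heavy-weight caveat above; the propensity
truncation bound is the operative guard and is always recorded in the run
manifest.
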
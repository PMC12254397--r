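#' Fit nuisance functions for natural effect estimation
#'
#' Estimates every nuisance function required by the one-step natural
#' direct/indirect effect estimator for a single trait and a single mediator:
#' \describe{
#'   \item{g}{the exposure propensity \eqn{P(A = 1 \mid W)};}
#'   \item{e}{the mediator-conditional propensity \eqn{P(A = 1 \mid M, W)},
#'     whose ratio against g re-expresses the mediator density ratio without
#'     estimating conditional densities of a continuous mediator;}
#'   \item{mu}{the outcome regressions \eqn{E[Y \mid A = a, M, W]}, fit
#'     separately within each exposure arm;}
#'   \item{eta}{the pseudo-outcome regressions
#'     \eqn{E[\mu(a, M, W) \mid A = a', W]}, fit by regressing the predicted
#'     \eqn{\mu(a, M_i, W_i)} on W among subjects with \eqn{A = a'}, for the
#'     three pairs (a, a') needed by \eqn{\psi(1,1)}, \eqn{\psi(1,0)} and
#'     \eqn{\psi(0,0)}.}
#' }
#' All nuisances are fit with the Super Learner over `library`. With
#' `cross_fit = TRUE` (default, required for valid Wald inference with
#' adaptive learners) every subject's predictions come from fits that exclude
#' that subject's fold. Estimated propensities are truncated to
#' `[delta, 1 - delta]`.
#'
#' @param cohort Cohort tibble, already complete-case filtered on
#'   `confounders`, `A`, `mediator` and `trait` (missing values error).
#' @param trait,mediator Column names of the outcome and the mediator.
#' @param confounders Character vector of confounder column names.
#' @param library Learner library (list of `learner_spec`).
#' @param K Folds for cross-fitting, shared with the Super Learner.
#' @param seed Integer seed.
#' @param cross_fit Use out-of-fold nuisance predictions?
#' @param delta Symmetric propensity truncation bound (0 disables).
#' @param clip_eps Probability clipping inside the binary Super Learner
#'   (see [sl_predict()]); set to 0 together with `delta = 0` for exact
#'   nonparametric (saturated) fits.
#' @param stratify_cv Balance folds on the exposure (recommended for rare
#'   exposures)?
#' @return A `nuisance_fits` object with per-subject prediction vectors.
#' @seealso [counterfactual_mean_onestep()], [estimate_nde_nie()]
#' @export
fit_nuisances <- function(cohort, trait, mediator, confounders,
                          library = default_learner_library(), K = 10,
                          seed = 1L, cross_fit = TRUE, delta = 0.025,
                          clip_eps = 0.001, stratify_cv = TRUE) {
  need <- c(confounders, "A", mediator, trait)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mediscreen_input_error")
  }
  if (anyNA(cohort[need])) {
    abort("cohort must be complete-case filtered before nuisance fitting",
          class = "mediscreen_input_error")
  }
  A <- cohort$A
  if (!all(A %in% c(0, 1))) abort("exposure A must be binary 0/1")
  n <- nrow(cohort)
  for (a in 0:1) {
    if (sum(A == a) == 0) {
      abort(sprintf("no subjects with A = %d in this analysis stratum", a),
            class = "mediscreen_estimation_error")
    }
  }

  W <- as_num_matrix(cohort[confounders])
  MW <- as_num_matrix(cohort[c(mediator, confounders)])
  Y <- cohort[[trait]]

  folds <- if (cross_fit) {
    make_folds(n, K, stratify_labels = if (stratify_cv) A else NULL,
               seed = seed)
  } else {
    rep(1L, n)
  }
  fold_ids <- sort(unique(folds))

  g1 <- e1 <- mu0 <- mu1 <- numeric(n)
  eta <- list(a1_ap0 = numeric(n), a0_ap0 = numeric(n), a1_ap1 = numeric(n))

  sl <- function(x, y, family, sub_seed) {
    fit_superlearner(x, y, library = library, K = K, family = family,
                     seed = sub_seed, stratify_cv = family == "binary" && stratify_cv,
                     clip_eps = clip_eps)
  }

  for (k in fold_ids) {
    tr <- if (cross_fit) folds != k else rep(TRUE, n)
    te <- folds == k
    if (sum(A[tr] == 1) == 0 || sum(A[tr] == 0) == 0) {
      abort("a training fold lost all cases or controls; reduce K or stratify folds",
            class = "mediscreen_estimation_error")
    }

    g_fit <- sl(W[tr, , drop = FALSE], A[tr], "binary", seed + 101L * k)
    g1[te] <- sl_predict(g_fit, W[te, , drop = FALSE])

    e_fit <- sl(MW[tr, , drop = FALSE], A[tr], "binary", seed + 103L * k)
    e1[te] <- sl_predict(e_fit, MW[te, , drop = FALSE])

    pseudo <- list()
    for (a in 0:1) {
      arm <- tr & A == a
      mu_fit <- sl(MW[arm, , drop = FALSE], Y[arm], "continuous",
                   seed + 107L * k + a)
      if (a == 0) {
        mu0[te] <- sl_predict(mu_fit, MW[te, , drop = FALSE])
      } else {
        mu1[te] <- sl_predict(mu_fit, MW[te, , drop = FALSE])
      }
      # pseudo-outcomes on the training rows for the eta regressions
      pseudo[[a + 1]] <- sl_predict(mu_fit, MW[tr, , drop = FALSE])
    }

    eta_pairs <- list(a1_ap0 = c(1, 0), a0_ap0 = c(0, 0), a1_ap1 = c(1, 1))
    for (nm in names(eta_pairs)) {
      a <- eta_pairs[[nm]][1]
      ap <- eta_pairs[[nm]][2]
      rows <- A[tr] == ap
      eta_fit <- sl(W[tr, , drop = FALSE][rows, , drop = FALSE],
                    pseudo[[a + 1]][rows], "continuous",
                    seed + 109L * k + a * 2L + ap)
      eta[[nm]][te] <- sl_predict(eta_fit, W[te, , drop = FALSE])
    }
  }

  if (delta > 0) {
    g1 <- pmin(pmax(g1, delta), 1 - delta)
    e1 <- pmin(pmax(e1, delta), 1 - delta)
  }

  structure(
    list(
      g1 = g1, e1 = e1, mu0 = mu0, mu1 = mu1, eta = eta,
      folds = folds, delta = delta, trait = trait, mediator = mediator,
      confounders = confounders, cross_fit = cross_fit, n = n
    ),
    class = "nuisance_fits"
  )
}

#' @export
print.nuisance_fits <- function(x, ...) {
  cat(sprintf(
    "<nuisance_fits> trait '%s', mediator '%s', n = %d, %s, delta = %g\n",
    x$trait, x$mediator, x$n,
    if (x$cross_fit) sprintf("cross-fit (%d folds)", length(unique(x$folds)))
    else "no cross-fitting",
    x$delta
  ))
  invisible(x)
}

new_effect_estimate <- function(estimand, D) {
  point <- mean(D)
  eif <- D - point
  inf <- wald_inference(point, eif)
  structure(
    c(list(estimand = estimand, estimate = point, eif_values = eif,
           n_used = length(D)), inf),
    class = "effect_estimate"
  )
}

#' Wald inference from influence values
#'
#' Standard error, 95% confidence interval, z statistic and two-sided normal
#' p-value for a one-step estimate, from the sample standard deviation of its
#' (centred) influence values: `se = sd(eif) / sqrt(n)`. A constant influence
#' vector gives `se = 0` and is reported with a degenerate-inference warning
#' (`p = 0` unless the point estimate is itself 0).
#'
#' @param point Point estimate.
#' @param eif_values Per-subject influence values (length `n >= 2`).
#' @return List with `se`, `ci_lo`, `ci_hi`, `z`, `p`.
#' @export
wald_inference <- function(point, eif_values) {
  n <- length(eif_values)
  if (n < 2) abort("need at least 2 influence values")
  se <- sd(eif_values) / sqrt(n)
  if (se == 0) {
    warn("constant influence values: degenerate Wald inference")
    z <- if (point == 0) 0 else sign(point) * Inf
    p <- if (point == 0) 1 else 0
  } else {
    z <- point / se
    p <- 2 * (1 - pnorm(abs(z)))
  }
  list(se = se, ci_lo = point - 1.96 * se, ci_hi = point + 1.96 * se,
       z = z, p = p)
}

#' One-step estimate of a counterfactual mean E[Y(a, M(a'))]
#'
#' The cross-world counterfactual mean \eqn{\psi(a, a') = E[Y(a, M(a'))]} is
#' estimated as the empirical mean of the uncentred efficient influence
#' function
#' \deqn{D_i = \frac{1\{A_i = a\}}{g(a \mid W_i)} r(M_i, W_i)
#'   (Y_i - \mu(a, M_i, W_i)) + \frac{1\{A_i = a'\}}{g(a' \mid W_i)}
#'   (\mu(a, M_i, W_i) - \eta(a'; a, W_i)) + \eta(a'; a, W_i),}
#' where the mediator density ratio is re-expressed through propensities
#' (Bayes factorisation):
#' \deqn{r(M, W) = \frac{e(a' \mid M, W)}{e(a \mid M, W)} \cdot
#'   \frac{g(a \mid W)}{g(a' \mid W)},}
#' and \eqn{r \equiv 1} when `a == a_prime` (the estimator then reduces to
#' augmented inverse probability weighting for \eqn{E[Y(a)]}).
#'
#' @param a,a_prime Exposure levels in \{0, 1\}: the arm whose outcome
#'   mechanism is evaluated (`a`) and the arm whose mediator distribution is
#'   imposed (`a_prime`).
#' @param cohort The cohort used to fit `nuisances` (same rows, same order).
#' @param nuisances A [fit_nuisances()] result.
#' @return An `effect_estimate` with point estimate, per-subject influence
#'   values, `se`, 95% CI, `z` and two-sided normal `p`.
#' @export
counterfactual_mean_onestep <- function(a, a_prime, cohort, nuisances) {
  stopifnot(inherits(nuisances, "nuisance_fits"),
            a %in% c(0, 1), a_prime %in% c(0, 1))
  if (nrow(cohort) != nuisances$n) {
    abort("cohort and nuisances disagree on sample size",
          class = "mediscreen_input_error")
  }
  D <- psi_uncentered_eif(a, a_prime, cohort, nuisances)
  new_effect_estimate(sprintf("psi(%d,%d)", a, a_prime), D)
}

psi_uncentered_eif <- function(a, a_prime, cohort, nuis) {
  A <- cohort$A
  Y <- cohort[[nuis$trait]]
  g_a <- if (a == 1) nuis$g1 else 1 - nuis$g1
  g_ap <- if (a_prime == 1) nuis$g1 else 1 - nuis$g1
  mu_a <- if (a == 1) nuis$mu1 else nuis$mu0
  if (any(g_a <= 0) || any(g_ap <= 0)) {
    abort("zero estimated propensity encountered; enable truncation (delta > 0)",
          class = "mediscreen_estimation_error")
  }
  if (a == a_prime) {
    r <- 1
  } else {
    e_a <- if (a == 1) nuis$e1 else 1 - nuis$e1
    e_ap <- if (a_prime == 1) nuis$e1 else 1 - nuis$e1
    if (any(e_a <= 0)) {
      abort("zero estimated mediator-conditional propensity; enable truncation",
            class = "mediscreen_estimation_error")
    }
    r <- (e_ap / e_a) * (g_a / g_ap)
  }
  key <- sprintf("a%d_ap%d", a, a_prime)
  eta_v <- nuis$eta[[key]]
  if (is.null(eta_v)) {
    abort(sprintf("no eta regression stored for (a = %d, a' = %d)", a, a_prime))
  }
  (A == a) / g_a * r * (Y - mu_a) +
    (A == a_prime) / g_ap * (mu_a - eta_v) +
    eta_v
}

#' Natural direct and indirect effects by one-step estimation
#'
#' Computes the three counterfactual means \eqn{\psi(1,1)}, \eqn{\psi(1,0)}
#' and \eqn{\psi(0,0)} from a shared set of nuisance fits and differences
#' them (the "mediation formula" decomposition):
#' \deqn{NDE = \psi(1,0) - \psi(0,0), \quad NIE = \psi(1,1) - \psi(1,0),
#'   \quad TE = \psi(1,1) - \psi(0,0).}
#' Influence values of each contrast are the differences of the component
#' uncentred influence functions, so `NDE + NIE = TE_mediation` holds to
#' machine precision by construction.
#'
#' @inheritParams counterfactual_mean_onestep
#' @return A list of class `mediation_estimates` with `effect_estimate`
#'   elements `NDE`, `NIE`, `TE_mediation`, and the component `psi`
#'   estimates.
#' @examples
#' sim <- generate_cohort(sem_config(
#'   n_cases = 150, n_controls = 850, missing_mediator = 0, missing_trait = 0,
#'   special_code_rate = 0, seed = 3
#' ))
#' nuis <- fit_nuisances(sim$cohort, "trait_01", "activity", c("age", "sex"),
#'                       library = fast_learner_library(), K = 5, seed = 3)
#' est <- estimate_nde_nie(sim$cohort, nuis)
#' tidy(est$NDE)
#' @export
estimate_nde_nie <- function(cohort, nuisances) {
  D11 <- psi_uncentered_eif(1, 1, cohort, nuisances)
  D10 <- psi_uncentered_eif(1, 0, cohort, nuisances)
  D00 <- psi_uncentered_eif(0, 0, cohort, nuisances)
  structure(
    list(
      NDE = new_effect_estimate("NDE", D10 - D00),
      NIE = new_effect_estimate("NIE", D11 - D10),
      TE_mediation = new_effect_estimate("TE_mediation", D11 - D00),
      psi = list(
        psi11 = new_effect_estimate("psi(1,1)", D11),
        psi10 = new_effect_estimate("psi(1,0)", D10),
        psi00 = new_effect_estimate("psi(0,0)", D00)
      )
    ),
    class = "mediation_estimates"
  )
}

#' @export
print.mediation_estimates <- function(x, ...) {
  print(dplyr::bind_rows(lapply(x[c("NDE", "NIE", "TE_mediation")], tidy)))
  invisible(x)
}

#' @describeIn estimate_nde_nie One row per estimand (NDE, NIE,
#'   TE_mediation) in broom column conventions.
#' @param x A `mediation_estimates` object.
#' @param ... Unused.
#' @method tidy mediation_estimates
#' @export
tidy.mediation_estimates <- function(x, ...) {
  dplyr::bind_rows(lapply(x[c("NDE", "NIE", "TE_mediation")], tidy))
}

#' Total effect by augmented inverse probability weighting
#'
#' One-step (AIPW, doubly robust) estimator of the average total effect
#' \eqn{E[Y(1)] - E[Y(0)]}:
#' \deqn{\hat\tau = \frac{1}{n} \sum_i \left[ \left(\frac{A_i}{g(1|W_i)} -
#'   \frac{1 - A_i}{g(0|W_i)}\right) (Y_i - b(A_i, W_i)) + b(1, W_i) -
#'   b(0, W_i) \right],}
#' with propensity `g` and arm-wise outcome regressions `b` fit by the Super
#' Learner with cross-fitting. The mediator is not required, so the total
#' effect uses the larger complete-case sample on (confounders, exposure,
#' outcome) only.
#'
#' @inheritParams fit_nuisances
#' @param nuisances Optional pre-computed nuisances: a list with per-subject
#'   vectors `g1`, `b0`, `b1` (e.g. known randomisation probabilities). When
#'   supplied no models are fit.
#' @return An `effect_estimate` for the total effect.
#' @export
estimate_te_aipw <- function(cohort, trait, confounders,
                             library = default_learner_library(), K = 10,
                             seed = 1L, cross_fit = TRUE, delta = 0.025,
                             clip_eps = 0.001, stratify_cv = TRUE,
                             nuisances = NULL) {
  need <- c(confounders, "A", trait)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mediscreen_input_error")
  }
  if (anyNA(cohort[need])) {
    abort("cohort must be complete-case filtered before estimation",
          class = "mediscreen_input_error")
  }
  A <- cohort$A
  Y <- cohort[[trait]]
  n <- nrow(cohort)
  for (a in 0:1) {
    if (sum(A == a) == 0) {
      abort(sprintf("no subjects with A = %d in this analysis stratum", a),
            class = "mediscreen_estimation_error")
    }
  }

  if (is.null(nuisances)) {
    W <- as_num_matrix(cohort[confounders])
    folds <- if (cross_fit) {
      make_folds(n, K, stratify_labels = if (stratify_cv) A else NULL,
                 seed = seed)
    } else {
      rep(1L, n)
    }
    g1 <- b0 <- b1 <- numeric(n)
    for (k in sort(unique(folds))) {
      tr <- if (cross_fit) folds != k else rep(TRUE, n)
      te <- folds == k
      g_fit <- fit_superlearner(W[tr, , drop = FALSE], A[tr], library, K,
                                "binary", seed + 211L * k,
                                stratify_cv = stratify_cv, clip_eps = clip_eps)
      g1[te] <- sl_predict(g_fit, W[te, , drop = FALSE])
      for (a in 0:1) {
        arm <- tr & A == a
        b_fit <- fit_superlearner(W[arm, , drop = FALSE], Y[arm], library, K,
                                  "continuous", seed + 223L * k + a,
                                  clip_eps = clip_eps)
        if (a == 0) {
          b0[te] <- sl_predict(b_fit, W[te, , drop = FALSE])
        } else {
          b1[te] <- sl_predict(b_fit, W[te, , drop = FALSE])
        }
      }
    }
    if (delta > 0) g1 <- pmin(pmax(g1, delta), 1 - delta)
  } else {
    g1 <- rep_len(nuisances$g1, n)
    b0 <- rep_len(nuisances$b0, n)
    b1 <- rep_len(nuisances$b1, n)
  }
  g0 <- 1 - g1
  if (any(g1 <= 0) || any(g0 <= 0)) {
    abort("zero estimated propensity encountered; enable truncation (delta > 0)",
          class = "mediscreen_estimation_error")
  }
  bA <- ifelse(A == 1, b1, b0)
  D <- (A / g1 - (1 - A) / g0) * (Y - bA) + b1 - b0
  new_effect_estimate("TE", D)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate> %s = %.4g (se %.3g, 95%% CI [%.4g, %.4g], z = %.3g, p = %.3g, n = %d)\n",
    x$estimand, x$estimate, x$se, x$ci_lo, x$ci_hi, x$z, x$p, x$n_used
  ))
  invisible(x)
}

#' Tidy an effect estimate
#'
#' @param x An `effect_estimate`.
#' @param ... Unused.
#' @return One-row tibble with broom-style columns `estimand`, `estimate`,
#'   `std.error`, `statistic` (z), `p.value`, `conf.low`, `conf.high`,
#'   `n_used`.
#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::tibble(
    estimand = x$estimand, estimate = x$estimate, std.error = x$se,
    statistic = x$z, p.value = x$p, conf.low = x$ci_lo, conf.high = x$ci_hi,
    n_used = x$n_used
  )
}

#' @describeIn tidy.effect_estimate One-row summary identical to `tidy()`
#'   minus the interval columns.
#' @method glance effect_estimate
#' @export
glance.effect_estimate <- function(x, ...) {
  tibble::tibble(estimand = x$estimand, estimate = x$estimate,
                 std.error = x$se, statistic = x$z, p.value = x$p,
                 n_used = x$n_used)
}
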
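# Saturated nuisances on all-binary data: fits are exact empirical
# frequencies and the one-step estimator must coincide with exhaustive
# g-computation (the influence-function correction averages to zero at the
# nonparametric MLE).
saturated_nuisances <- function(dat) {
  fit_nuisances(dat, "Y", "M", "W", library = list(lrn_saturated()),
                cross_fit = FALSE, delta = 0, clip_eps = 0, K = 2)
}

test_that("saturated nuisances equal empirical conditional frequencies", {
  dat <- make_binary_cohort(400)
  nuis <- saturated_nuisances(dat)
  for (w in 0:1) {
    rows <- dat$W == w
    expect_equal(unique(nuis$g1[rows]), mean(dat$A[rows]))
    for (m in 0:1) {
      cell <- rows & dat$M == m
      expect_equal(unique(nuis$e1[cell]), mean(dat$A[cell]))
      expect_equal(unique(nuis$mu1[cell]),
                   mean(dat$Y[dat$A == 1 & dat$M == m & dat$W == w]))
      expect_equal(unique(nuis$mu0[cell]),
                   mean(dat$Y[dat$A == 0 & dat$M == m & dat$W == w]))
    }
  }
})

test_that("one-step counterfactual means match exhaustive g-computation", {
  for (seed in c(11, 47)) {
    dat <- make_binary_cohort(500, seed = seed)
    nuis <- saturated_nuisances(dat)
    for (pair in list(c(1, 0), c(0, 0), c(1, 1))) {
      est <- counterfactual_mean_onestep(pair[1], pair[2], dat, nuis)
      expect_lt(abs(est$estimate - oracle_gcomp_psi(dat, pair[1], pair[2])),
                1e-10)
    }
    te <- estimate_te_aipw(dat, "Y", "W", library = list(lrn_saturated()),
                           cross_fit = FALSE, delta = 0, clip_eps = 0, K = 2)
    expect_lt(abs(te$estimate - oracle_gcomp_te(dat)), 1e-10)
  }
})

test_that("psi(a, a) reduces to AIPW for E[Y(a)]", {
  dat <- make_binary_cohort(300)
  nuis <- saturated_nuisances(dat)
  est <- counterfactual_mean_onestep(1, 1, dat, nuis)
  # direct AIPW for E[Y(1)] with b(1, W) = eta(1;1,W)
  aipw <- mean(dat$A / nuis$g1 * (dat$Y - nuis$mu1) +
                 dat$A / nuis$g1 * (nuis$mu1 - nuis$eta$a1_ap1) +
                 nuis$eta$a1_ap1)
  expect_equal(est$estimate, aipw, tolerance = 1e-12)
})

test_that("NDE + NIE equals the mediation total effect identically", {
  sim <- generate_cohort(clean_sem(150, 850, one_trait_beta(), seed = 21))
  nuis <- fit_nuisances(sim$cohort, "t1", "activity", c("age", "sex"),
                        library = fast_learner_library(), K = 5, seed = 21)
  est <- estimate_nde_nie(sim$cohort, nuis)
  expect_lt(abs(est$NDE$estimate + est$NIE$estimate -
                  est$TE_mediation$estimate), 1e-12)
  # the eif decomposition is consistent too
  expect_lt(max(abs(est$NDE$eif_values + est$NIE$eif_values -
                      est$TE_mediation$eif_values)), 1e-12)
})

test_that("known randomisation nuisances reduce AIPW to Horvitz-Thompson", {
  set.seed(14)
  n <- 200
  dat <- tibble::tibble(age = runif(n, 40, 69), A = rbinom(n, 1, 0.5),
                        y = rnorm(n))
  est <- estimate_te_aipw(dat, "y", "age",
                          nuisances = list(g1 = 0.5, b0 = 0, b1 = 0))
  ht <- mean(dat$A * dat$y / 0.5) - mean((1 - dat$A) * dat$y / 0.5)
  expect_equal(est$estimate, ht, tolerance = 1e-12)
})

test_that("linear SEM effects are recovered without material bias", {
  # 40 replicates at n = 2500: mean estimate within 3 Monte-Carlo SEs of the
  # closed-form truths (full 200-replicate calibration runs in the
  # acceptance suite)
  beta <- one_trait_beta(bA = 0.5, bM = 0.02)
  truth_nde <- 0.5
  truth_nie <- 0.02 * -11.3
  reps <- t(vapply(1:40, function(r) {
    sim <- generate_cohort(clean_sem(250, 2250, beta, seed = 1000 + r))
    nuis <- fit_nuisances(sim$cohort, "t1", "activity", c("age", "sex"),
                          library = fast_learner_library(), K = 5,
                          seed = 1000 + r)
    est <- estimate_nde_nie(sim$cohort, nuis)
    te <- estimate_te_aipw(sim$cohort, "t1", c("age", "sex"),
                           library = fast_learner_library(), K = 5,
                           seed = 1000 + r)
    c(nde = est$NDE$estimate, nie = est$NIE$estimate, te = te$estimate,
      te_med = est$TE_mediation$estimate, te_med_se = est$TE_mediation$se)
  }, numeric(5)))
  mc_se <- function(v) sd(v) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps[, "nde"]) - truth_nde), 3 * mc_se(reps[, "nde"]))
  expect_lt(abs(mean(reps[, "nie"]) - truth_nie), 3 * mc_se(reps[, "nie"]))
  expect_lt(abs(mean(reps[, "te"]) - (truth_nde + truth_nie)),
            3 * mc_se(reps[, "te"]))
  # the AIPW total effect and the mediation-formula total effect agree
  gap <- reps[, "te"] - reps[, "te_med"]
  expect_lt(abs(mean(gap)), 3 * sd(gap) / sqrt(nrow(reps)) + 0.01)
})

test_that("a null exposure-mediator path gives a null indirect effect", {
  beta <- one_trait_beta(bA = 0.4, bM = 0.05)
  nie_z <- vapply(1:10, function(r) {
    cfg <- clean_sem(250, 2250, beta, seed = 300 + r,
                     alpha = c(intercept = 60, A = 0, age = -0.2, sex = 0.5))
    sim <- generate_cohort(cfg)
    nuis <- fit_nuisances(sim$cohort, "t1", "activity", c("age", "sex"),
                          library = fast_learner_library(), K = 5,
                          seed = 300 + r)
    est <- estimate_nde_nie(sim$cohort, nuis)
    est$NIE$estimate / est$NIE$se
  }, numeric(1))
  # z-scores behave as standard normal draws under the null
  expect_lt(abs(mean(nie_z)), 3 / sqrt(10))
})

test_that("wald inference matches its definition and handles degeneracy", {
  eif <- scale(rnorm(100))[, 1] # exactly mean 0, sd 1
  inf <- wald_inference(0.196, eif)
  expect_equal(inf$se, 0.1)
  expect_equal(inf$z, 1.96)
  expect_equal(inf$p, 2 * (1 - pnorm(1.96)), tolerance = 1e-12)
  expect_equal(inf$ci_lo, 0.196 - 1.96 * 0.1)

  inf0 <- wald_inference(0, eif)
  expect_identical(inf0$z, 0)
  expect_identical(inf0$p, 1)

  expect_warning(infc <- wald_inference(0.5, rep(0, 10)), "degenerate")
  expect_identical(infc$se, 0)
  expect_identical(infc$p, 0)
})

test_that("estimates are invariant to row order", {
  sim <- generate_cohort(clean_sem(100, 400, one_trait_beta(), seed = 33))
  co <- sim$cohort
  perm <- sample(nrow(co))
  args <- list(trait = "t1", mediator = "activity",
               confounders = c("age", "sex"),
               library = fast_learner_library(), cross_fit = FALSE, K = 2,
               seed = 33)
  e1 <- estimate_nde_nie(co, do.call(fit_nuisances, c(list(co), args)))
  co2 <- co[perm, ]
  e2 <- estimate_nde_nie(co2, do.call(fit_nuisances, c(list(co2), args)))
  expect_equal(e1$NDE$estimate, e2$NDE$estimate, tolerance = 1e-10)
  expect_equal(e1$NIE$estimate, e2$NIE$estimate, tolerance = 1e-10)
})

test_that("AIPW is doubly robust where the plug-in is not", {
  # with a deliberately wrong outcome regression (b = 0) but the true
  # propensity, the AIPW bias shrinks with n; the plug-in stays at -TE
  beta <- one_trait_beta(bA = 1, bM = 0)
  bias_at <- function(n, reps, seed0) {
    mean(vapply(seq_len(reps), function(r) {
      cfg <- clean_sem(n / 2, n / 2, beta, seed = seed0 + r,
                       gamma = c(intercept = 0, age = 0, sex = 0))
      sim <- generate_cohort(cfg)
      est <- estimate_te_aipw(sim$cohort, "t1", c("age", "sex"),
                              nuisances = list(g1 = 0.5, b0 = 0, b1 = 0))
      est$estimate - 1
    }, numeric(1)))
  }
  b_small <- bias_at(250, 10, 500)
  b_large <- bias_at(4000, 10, 600)
  expect_lt(abs(b_large), abs(b_small))
  # the plug-in under the same wrong regression estimates mean(b1 - b0) = 0,
  # i.e. its bias stays at the full effect size 1 regardless of n
  expect_lt(abs(b_large), 0.1)
})

test_that("preconditions are enforced", {
  sim <- generate_cohort(sem_config(n_cases = 50, n_controls = 450, seed = 2,
                                    beta = one_trait_beta()))
  expect_error(
    fit_nuisances(sim$cohort, "t1", "activity", c("age", "sex"),
                  library = fast_learner_library(), K = 2),
    "complete-case"
  )
  co <- generate_cohort(clean_sem(50, 450, one_trait_beta(), seed = 2))$cohort
  co0 <- co[co$A == 0, ]
  expect_error(
    fit_nuisances(co0, "t1", "activity", c("age", "sex"),
                  library = fast_learner_library(), K = 2),
    "A = 1", class = "mediscreen_estimation_error"
  )
  expect_error(
    fit_nuisances(co, "t1", "nope", c("age", "sex"),
                  library = fast_learner_library(), K = 2),
    "missing columns"
  )
})
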
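fast_cfg <- function(...) {
  screen_config(library = fast_learner_library(), K = 3, ...)
}

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  # hand-evaluated step-up: all four adjusted to 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(17)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1) # skewed mixtures too
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }

  # NA handling: excluded from the family then reinserted
  p <- c(0.01, NA, 0.04, 0.03, NA)
  got <- bh_adjust(p)
  expect_true(all(is.na(got[c(2, 5)])))
  expect_equal(got[!is.na(p)], oracle_bh(p[!is.na(p)]))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mediscreen_input_error")
})

test_that("BH rejection count equals the largest step-up index", {
  set.seed(23)
  for (i in 1:50) {
    m <- sample(5:60, 1)
    p <- c(runif(ceiling(m / 2))^3, runif(floor(m / 2)))
    adj <- bh_adjust(p)
    sorted <- sort(p)
    k <- max(c(0L, which(sorted <= 0.05 * seq_len(m) / m)))
    expect_identical(sum(adj < 0.05), as.integer(k))
  }
})

test_that("the screen emits one row per cell and is deterministic", {
  beta <- data.frame(trait = c("t1", "t2"), intercept = 0, A = c(0.8, 0),
                     M = 0, age = 0.005, sex = 0.1, sigma = 1)
  sim <- generate_cohort(clean_sem(200, 1300, beta, seed = 6))
  cfg <- fast_cfg(seed = 6)
  res <- run_screen(sim$cohort, c("t1", "t2"), mediators = "activity",
                    strata = c("combined", "female"),
                    estimands = c("TE", "NDE", "NIE"), config = cfg)
  expect_s3_class(res, "trait_results")
  expect_identical(nrow(res), 2L * 2L * 1L * 3L)
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  expect_identical(res$significant, !is.na(res$p_adj) & res$p_adj < 0.05)
  # fractions on NDE/NIE rows sum to one where defined
  fr <- res[res$estimand != "TE" & !is.na(res$nde_fraction), ]
  expect_equal(fr$nde_fraction + fr$nie_fraction, rep(1, nrow(fr)))

  res2 <- run_screen(sim$cohort, c("t1", "t2"), mediators = "activity",
                     strata = c("combined", "female"),
                     estimands = c("TE", "NDE", "NIE"), config = cfg)
  expect_identical(res, res2)
})

test_that("large direct effects are detected while null indirects are not", {
  beta <- data.frame(trait = paste0("t", 1:4), intercept = 0,
                     A = c(1, 1, 0, 0), M = 0, age = 0.005, sex = 0.1,
                     sigma = 1)
  sim <- generate_cohort(clean_sem(400, 3600, beta, seed = 19))
  res <- run_screen(sim$cohort, paste0("t", 1:4), strata = "combined",
                    estimands = c("NDE", "NIE"), config = fast_cfg(seed = 19))
  nde <- res[res$estimand == "NDE", ]
  nie <- res[res$estimand == "NIE", ]
  expect_true(all(nde$significant[nde$trait %in% c("t1", "t2")]))
  expect_false(any(nie$significant))
})

test_that("a stratum without cases yields a flagged missing row", {
  beta <- one_trait_beta()
  sim <- generate_cohort(clean_sem(60, 440, beta, seed = 9))
  co <- sim$cohort[!(sim$cohort$A == 1 & sim$cohort$sex == 0), ]
  expect_warning(
    res <- run_screen(co, "t1", strata = "male", estimands = "TE",
                      config = fast_cfg(seed = 9)),
    "no estimate"
  )
  expect_identical(nrow(res), 1L)
  expect_true(is.na(res$estimate))
  expect_false(res$significant)
})

test_that("global and per-analysis multiplicity families differ as expected", {
  p <- c(0.001, 0.02, 0.4, 0.009, 0.03, 0.6)
  res <- tibble::tibble(
    trait = rep(c("a", "b", "c"), 2),
    stratum = "combined",
    mediator = "m",
    estimand = rep(c("NDE", "NIE"), each = 3),
    p = p
  )
  per <- mediscreen:::apply_fdr(res, family_mode = "per-analysis")
  glob <- mediscreen:::apply_fdr(res, family_mode = "global")
  expect_equal(per$p_adj[per$estimand == "NDE"], bh_adjust(p[1:3]))
  expect_equal(glob$p_adj, bh_adjust(p))
})

test_that("effect fractions follow their definition with a floor", {
  expect_equal(effect_fractions(2, 2, 0), list(nde_fraction = 1,
                                               nie_fraction = 0))
  expect_equal(effect_fractions(2, 1.5, 0.5),
               list(nde_fraction = 0.75, nie_fraction = 0.25))
  fr <- effect_fractions(1e-12, 5e-13, 5e-13)
  expect_true(is.na(fr$nde_fraction))
})

test_that("z-score concordance classifies traits and detects shared effects", {
  mk <- function(z, sig) {
    tibble::tibble(trait = paste0("t", seq_along(z)), estimand = "NDE",
                   mediator = "activity", z = z, significant = sig)
  }
  # identical tables: r = 1, classes all both/neither
  za <- c(3, -2.5, 0.4, 1.1, -0.2)
  sig <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  conc <- zscore_concordance(mk(za, sig), mk(za, sig))
  expect_equal(conc$pearson_r, 1)
  expect_true(all(conc$classes$class %in% c("both", "neither")))

  # independent null z-scores at m = 100: |r| stays small
  set.seed(41)
  c0 <- zscore_concordance(mk(rnorm(100), rep(FALSE, 100)),
                           mk(rnorm(100), rep(FALSE, 100)))
  expect_lt(abs(c0$pearson_r), 0.3)

  # shared true effects across strata: strongly positive r
  shared <- rnorm(60, 0, 2)
  c1 <- zscore_concordance(mk(shared + rnorm(60, 0, 0.7), rep(FALSE, 60)),
                           mk(shared + rnorm(60, 0, 0.7), rep(FALSE, 60)))
  expect_gt(c1$pearson_r, 0.5)
  expect_lt(c1$p, 0.001)

  expect_error(zscore_concordance(mk(c(1, 2), c(TRUE, FALSE)),
                                  mk(c(1, 2), c(TRUE, FALSE))),
               class = "mediscreen_input_error")
})

test_that("the subgroup split matches arm sizes and keeps controls disjoint", {
  beta <- data.frame(trait = c("t1", "t2", "t3"), intercept = 0,
                     A = c(1.2, 0.2, -0.5), M = 0, age = 0.005, sex = 0.1,
                     sigma = 1)
  cfg <- clean_sem(550, 3000, beta, seed = 27)
  cfg$pem_rate <- 0.55
  sim <- generate_cohort(cfg)
  # amplify effects in the flagged subgroup (two-regime truth)
  co <- sim$cohort
  flagged_case <- co$A == 1 & co$pem_flag == 1
  co$t1[flagged_case] <- co$t1[flagged_case] + 1
  co$t2[flagged_case] <- co$t2[flagged_case] + 0.8
  co$t3[flagged_case] <- co$t3[flagged_case] - 0.8

  cmp <- pem_split_comparison(co, c("t1", "t2", "t3"),
                              config = fast_cfg(seed = 27), seed = 5)
  n_fl <- sum(co$A == 1 & co$pem_flag == 1)
  n_un <- sum(co$A == 1 & co$pem_flag == 0)
  expect_identical(cmp$n_arm, min(n_fl, n_un))
  expect_identical(sum(cmp$flagged$n_cases[1]), cmp$n_arm)
  # disjoint equal-size control sets
  expect_length(intersect(cmp$control_ids$arm1, cmp$control_ids$arm2), 0)
  expect_identical(length(cmp$control_ids$arm1),
                   length(cmp$control_ids$arm2))
  expect_lte(length(cmp$control_ids$arm1) + length(cmp$control_ids$arm2),
             sum(co$A == 0))
  # stronger effects in the flagged arm; no significantly opposing signs
  expect_gte(cmp$n_significant[["flagged"]], cmp$n_significant[["unflagged"]])
  both_sig <- merge(cmp$flagged, cmp$unflagged, by = "trait")
  both_sig <- both_sig[both_sig$significant.x & both_sig$significant.y, ]
  if (nrow(both_sig)) {
    expect_true(all(sign(both_sig$estimate.x) == sign(both_sig$estimate.y)))
  }
})

test_that("stringency sensitivity pairs z-scores across cohort variants", {
  beta <- data.frame(trait = c("t1", "t2", "t3"), intercept = 0,
                     A = c(0.9, -0.6, 0.4), M = 0, age = 0.005, sex = 0.1,
                     sigma = 1)
  sim <- generate_cohort(clean_sem(300, 2200, beta, seed = 31))
  co <- sim$cohort
  tr <- c("t1", "t2", "t3")

  # identical variants: r = 1, all points on the diagonal
  ss <- stringency_sensitivity(list(strict = co, lax = co), tr,
                               config = fast_cfg(seed = 31))
  expect_equal(ss$correlations$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ss$z_table$strict, ss$z_table$lax, tolerance = 1e-12)

  # attenuated variant: |z| systematically smaller
  att <- co
  att$t1 <- att$t1 - 0.6 * att$A * 0.9
  att$t2 <- att$t2 + 0.6 * att$A * 0.6
  att$t3 <- att$t3 - 0.6 * att$A * 0.4
  ss2 <- stringency_sensitivity(list(strict = co, lax = att), tr,
                                config = fast_cfg(seed = 31))
  expect_true(all(abs(ss2$z_table$lax) < abs(ss2$z_table$strict)))

  bad <- co[, setdiff(names(co), "t3")]
  expect_error(
    stringency_sensitivity(list(a = co, b = bad), tr,
                           config = fast_cfg(seed = 31)),
    "trait"
  )
})

test_that("screening independent null traits respects nominal FDR control", {
  # 5 null traits x 20 replicates of the NIE screen: the mean number of
  # FDR-significant indirect effects per family stays near its nominal bound
  beta <- data.frame(trait = paste0("t", 1:5), intercept = 0, A = 0.3,
                     M = 0.05, age = 0.005, sex = 0.1, sigma = 1)
  n_sig <- vapply(1:20, function(r) {
    cfg <- clean_sem(150, 1350, beta, seed = 700 + r,
                     alpha = c(intercept = 60, A = 0, age = -0.2, sex = 0.5))
    sim <- generate_cohort(cfg)
    res <- run_screen(sim$cohort, paste0("t", 1:5), strata = "combined",
                      estimands = "NIE", config = fast_cfg(seed = 700 + r))
    sum(res$significant)
  }, numeric(1))
  # 100 null tests in 20 families; binomial 3-sigma slack around 5%
  expect_lte(mean(n_sig), 0.05 * 5 + 3 * sqrt(0.05 * 0.95 * 5 / 20))
})
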
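#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Missing p-values are excluded from the family (they do not count towards
#' the number of tests) and reinserted as missing; non-missing values are
#' adjusted by the step-up rule `p_adj(i) = min_{j >= i} m p(j) / j` at
#' sorted positions, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "mediscreen_input_error")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Configuration for a screening run
#'
#' Collects the estimation and multiplicity settings shared by every cell of
#' a [run_screen()] analysis.
#'
#' @param library Learner library for all nuisance fits.
#' @param K Cross-validation / cross-fitting folds.
#' @param cross_fit Out-of-fold nuisance predictions (recommended)?
#' @param delta Propensity truncation bound.
#' @param clip_eps Probability clipping in binary Super Learner predictions.
#' @param stratify_cv Balance folds on the exposure?
#' @param winsor Length-1 or length-2 winsorization fractions applied to each
#'   trait within each analysis subset before estimation (0 = off).
#' @param fdr FDR threshold for significance flags.
#' @param family_mode `"per-analysis"` applies BH separately within each
#'   (stratum x estimand x mediator) family; `"global"` adjusts all rows
#'   together.
#' @param special_codes Mediator non-response codes removed before
#'   direct/indirect estimation.
#' @param te_floor Fractions of the total effect are reported only when
#'   `|TE_mediation|` exceeds this floor (avoids meaningless ratios at null
#'   traits).
#' @param seed Integer seed; the screen is deterministic given the seed.
#' @return A `screen_config` list.
#' @export
screen_config <- function(library = default_learner_library(), K = 10,
                          cross_fit = TRUE, delta = 0.025, clip_eps = 0.001,
                          stratify_cv = TRUE, winsor = 0, fdr = 0.05,
                          family_mode = c("per-analysis", "global"),
                          special_codes = c(-1, -3), te_floor = 1e-8,
                          seed = 1L) {
  family_mode <- match.arg(family_mode)
  if (fdr <= 0 || fdr >= 1) {
    abort("fdr threshold must lie in (0, 1)", class = "mediscreen_config_error")
  }
  winsor <- rep_len(winsor, 2)
  structure(
    list(library = library, K = K, cross_fit = cross_fit, delta = delta,
         clip_eps = clip_eps, stratify_cv = stratify_cv, winsor = winsor,
         fdr = fdr, family_mode = family_mode, special_codes = special_codes,
         te_floor = te_floor, seed = as.integer(seed)),
    class = "screen_config"
  )
}

stratum_subset <- function(cohort, stratum) {
  switch(stratum,
         combined = cohort,
         female = cohort[!is.na(cohort$sex) & cohort$sex == 1, , drop = FALSE],
         male = cohort[!is.na(cohort$sex) & cohort$sex == 0, , drop = FALSE],
         abort(paste0("unknown stratum: ", stratum),
               class = "mediscreen_config_error"))
}

stratum_confounders <- function(stratum, confounders) {
  # within a sex stratum, sex is constant and must leave the confounder set
  if (stratum == "combined") confounders else setdiff(confounders, "sex")
}

na_result_row <- function(trait, stratum, mediator, estimand, reason) {
  warn(sprintf("no estimate for %s / %s / %s / %s: %s",
               trait, stratum, mediator %||% "-", estimand, reason))
  tibble::tibble(
    trait = trait, stratum = stratum, mediator = mediator %||% NA_character_,
    estimand = estimand, n_cases = NA_integer_, n_controls = NA_integer_,
    estimate = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    z = NA_real_, p = NA_real_, cohens_d = NA_real_,
    nde_fraction = NA_real_, nie_fraction = NA_real_
  )
}

estimate_row <- function(est, trait, stratum, mediator, estimand,
                         n_cases, n_controls, d = NA_real_,
                         fr = c(NA_real_, NA_real_)) {
  tibble::tibble(
    trait = trait, stratum = stratum, mediator = mediator %||% NA_character_,
    estimand = estimand, n_cases = n_cases, n_controls = n_controls,
    estimate = est$estimate, se = est$se, ci_lo = est$ci_lo, ci_hi = est$ci_hi,
    z = est$z, p = est$p, cohens_d = d,
    nde_fraction = fr[1], nie_fraction = fr[2]
  )
}

#' Screen many traits for total, direct and indirect effects
#'
#' The full screening workflow: for every requested stratum (`combined`,
#' `female`, `male`), mediator and trait, the cohort is filtered (complete
#' cases per estimand; mediator non-response codes removed for mediation
#' estimands), the trait is optionally winsorized within the analysis
#' subset, effects are estimated by the one-step estimators, and
#' Benjamini-Hochberg adjustment is applied within each multiplicity family.
#' Sex-stratified analyses drop sex from the confounder set; the combined
#' analysis keeps it.
#'
#' Total effects use the AIPW estimator on the larger complete-case sample
#' (mediator not required); the `nde_fraction` / `nie_fraction` columns of
#' the NDE/NIE rows come from the shared-nuisance mediation run, for which
#' `NDE + NIE = TE` is exact. A cell that cannot be estimated (e.g. a
#' stratum with no cases for a trait) is emitted as a row of missing
#' estimates with a warning, never dropped silently.
#'
#' @param cohort Cohort tibble with columns `age`, `sex`, `A`, mediator and
#'   trait columns.
#' @param trait_specs Character vector of trait column names, or a list of
#'   [trait_spec()] objects (composites are computed first).
#' @param mediators Character vector of mediator column names.
#' @param strata Subset of `c("combined", "female", "male")`.
#' @param estimands Subset of `c("TE", "NDE", "NIE")`.
#' @param config A [screen_config()].
#' @param confounders Confounder set for the combined analysis.
#' @return A `trait_results` tibble with one row per
#'   (trait x stratum x mediator x estimand): estimates, Wald inference,
#'   `p_adj`, `significant`, Cohen's d and effect fractions.
#' @export
run_screen <- function(cohort, trait_specs, mediators = "activity",
                       strata = c("combined", "female", "male"),
                       estimands = c("TE", "NDE", "NIE"),
                       config = screen_config(),
                       confounders = c("age", "sex")) {
  stopifnot(inherits(config, "screen_config"))
  estimands <- match.arg(estimands, c("TE", "NDE", "NIE"), several.ok = TRUE)
  specs <- as_trait_specs(trait_specs)
  cohort <- build_trait_columns(cohort, specs)
  traits <- vapply(specs, `[[`, character(1), "name")

  rows <- list()
  for (stratum in strata) {
    sub <- stratum_subset(cohort, stratum)
    conf <- stratum_confounders(stratum, confounders)
    for (trait in traits) {
      ts <- specs[[match(trait, traits)]]
      sub_t <- sub
      wf <- config$winsor
      if (ts$winsor > 0) wf <- rep_len(ts$winsor, 2)
      if (any(wf > 0)) {
        sub_t[[trait]] <- winsorize(sub_t[[trait]], wf[1], wf[2])
      }

      d <- cohens_d(sub_t[[trait]][sub_t$A == 1], sub_t[[trait]][sub_t$A == 0])

      te_rows <- NULL
      if ("TE" %in% estimands) {
        te_cohort <- complete_case_filter(sub_t, c(conf, "A", trait))$cohort
        te_est <- tryCatch(
          estimate_te_aipw(te_cohort, trait, conf, library = config$library,
                           K = config$K, seed = config$seed,
                           cross_fit = config$cross_fit, delta = config$delta,
                           clip_eps = config$clip_eps,
                           stratify_cv = config$stratify_cv),
          error = identity
        )
        te_rows <- if (inherits(te_est, "error")) {
          list(est = NULL, reason = conditionMessage(te_est))
        } else {
          list(est = te_est,
               n_cases = sum(te_cohort$A == 1),
               n_controls = sum(te_cohort$A == 0))
        }
      }

      for (mediator in mediators) {
        if (!is.null(te_rows)) {
          rows[[length(rows) + 1]] <- if (is.null(te_rows$est)) {
            na_result_row(trait, stratum, mediator, "TE", te_rows$reason)
          } else {
            estimate_row(te_rows$est, trait, stratum, mediator, "TE",
                         te_rows$n_cases, te_rows$n_controls, d = d)
          }
        }
        if (any(c("NDE", "NIE") %in% estimands)) {
          med_cohort <- mediator_response_filter(sub_t, mediator,
                                                 config$special_codes)$cohort
          med_cohort <- complete_case_filter(
            med_cohort, c(conf, "A", mediator, trait)
          )$cohort
          med <- tryCatch({
            nuis <- fit_nuisances(med_cohort, trait, mediator, conf,
                                  library = config$library, K = config$K,
                                  seed = config$seed,
                                  cross_fit = config$cross_fit,
                                  delta = config$delta,
                                  clip_eps = config$clip_eps,
                                  stratify_cv = config$stratify_cv)
            estimate_nde_nie(med_cohort, nuis)
          }, error = identity)
          if (inherits(med, "error")) {
            for (estd in intersect(estimands, c("NDE", "NIE"))) {
              rows[[length(rows) + 1]] <-
                na_result_row(trait, stratum, mediator, estd,
                              conditionMessage(med))
            }
          } else {
            fr <- effect_fractions(med$TE_mediation$estimate,
                                   med$NDE$estimate, med$NIE$estimate,
                                   te_floor = config$te_floor)
            nc <- sum(med_cohort$A == 1)
            nu <- sum(med_cohort$A == 0)
            for (estd in intersect(estimands, c("NDE", "NIE"))) {
              rows[[length(rows) + 1]] <-
                estimate_row(med[[estd]], trait, stratum, mediator, estd,
                             nc, nu, d = d,
                             fr = c(fr$nde_fraction, fr$nie_fraction))
            }
          }
        }
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  out <- apply_fdr(out, fdr = config$fdr, family_mode = config$family_mode)
  class(out) <- c("trait_results", class(out))
  attr(out, "config") <- config
  out
}

# BH within multiplicity families; "per-analysis" = (stratum, estimand,
# mediator), the most conservative family consistent with per-analysis
# significance reporting. "global" pools every row.
apply_fdr <- function(results, fdr = 0.05,
                      family_mode = c("per-analysis", "global")) {
  family_mode <- match.arg(family_mode)
  if (family_mode == "global") {
    results$p_adj <- bh_adjust(results$p)
  } else {
    results <- results |>
      dplyr::group_by(.data$stratum, .data$estimand, .data$mediator) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  }
  results$significant <- !is.na(results$p_adj) & results$p_adj < fdr
  results
}

#' Direct and indirect effects as fractions of the total effect
#'
#' For a shared-nuisance mediation run (`nde + nie = te` exactly), the
#' fractions `nde/te` and `nie/te` always sum to 1 when defined. They are
#' reported as missing when `|te|` falls below `te_floor`.
#'
#' @param te,nde,nie Point estimates from one [estimate_nde_nie()] run.
#' @param te_floor Minimum `|te|` for a defined fraction.
#' @return List with `nde_fraction` and `nie_fraction`.
#' @export
effect_fractions <- function(te, nde, nie, te_floor = 1e-8) {
  if (is.na(te) || abs(te) < te_floor) {
    return(list(nde_fraction = NA_real_, nie_fraction = NA_real_))
  }
  list(nde_fraction = nde / te, nie_fraction = nie / te)
}

#' Concordance of z-scores between two screening analyses
#'
#' Pairs per-trait z-scores of a common estimand across two result tables
#' (e.g. female vs male strata), computes their Pearson correlation with its
#' test p-value, and classifies each trait by the two FDR significance flags.
#'
#' @param results_1,results_2 `trait_results` tibbles from [run_screen()]
#'   (or any tibble with `trait`, `estimand`, `z`, `significant`).
#' @param estimand Which estimand's z-scores to compare.
#' @param mediator Optional mediator filter (needed when tables span several
#'   mediators).
#' @param labels Length-2 names used in the per-trait classes.
#' @return List of class `zscore_concordance`: `pearson_r`, `p`, `n_traits`, and a
#'   `classes` tibble (`trait`, `z_1`, `z_2`, `class` in
#'   both/<label1>_only/<label2>_only/neither).
#' @export
zscore_concordance <- function(results_1, results_2, estimand = "NDE",
                               mediator = NULL,
                               labels = c("stratum1", "stratum2")) {
  pick <- function(res) {
    res <- dplyr::filter(res, .data$estimand == !!estimand)
    if (!is.null(mediator)) {
      res <- dplyr::filter(res, .data$mediator == !!mediator)
    }
    dplyr::select(res, "trait", "z", "significant")
  }
  paired <- dplyr::inner_join(pick(results_1), pick(results_2),
                              by = "trait", suffix = c("_1", "_2")) |>
    dplyr::filter(is.finite(.data$z_1), is.finite(.data$z_2))
  if (nrow(paired) < 3) {
    abort("need at least 3 paired traits with finite z-scores",
          class = "mediscreen_input_error")
  }
  ct <- cor.test(paired$z_1, paired$z_2, method = "pearson")
  classes <- paired |>
    dplyr::mutate(class = dplyr::case_when(
      .data$significant_1 & .data$significant_2 ~ "both",
      .data$significant_1 ~ paste0(labels[1], "_only"),
      .data$significant_2 ~ paste0(labels[2], "_only"),
      TRUE ~ "neither"
    )) |>
    dplyr::select("trait", z_1 = "z_1", z_2 = "z_2", "class")
  structure(
    list(pearson_r = unname(ct$estimate), p = ct$p.value,
         n_traits = nrow(paired), classes = classes, labels = labels,
         estimand = estimand),
    class = "zscore_concordance"
  )
}

#' @export
print.zscore_concordance <- function(x, ...) {
  cat(sprintf("<concordance> %s z-scores, %d traits: Pearson r = %.3f (p = %.3g)\n",
              x$estimand, x$n_traits, x$pearson_r, x$p))
  print(table(x$classes$class))
  invisible(x)
}

#' @describeIn zscore_concordance Per-trait paired z-scores and class.
#' @param x A `zscore_concordance` object.
#' @param ... Unused.
#' @method tidy zscore_concordance
#' @export
tidy.zscore_concordance <- function(x, ...) x$classes

#' @describeIn zscore_concordance One-row summary (r, p, n, class counts).
#' @method glance zscore_concordance
#' @export
glance.zscore_concordance <- function(x, ...) {
  tibble::tibble(
    pearson_r = x$pearson_r, p.value = x$p, n_traits = x$n_traits,
    n_both = sum(x$classes$class == "both"),
    n_neither = sum(x$classes$class == "neither")
  )
}

#' Matched subgroup comparison with disjoint controls
#'
#' Compares total effects between two case subgroups defined by a binary
#' flag (e.g. post-exertional malaise) under matched statistical power: the
#' larger case subgroup is randomly subsampled without replacement to the
#' smaller's size, controls are partitioned into two disjoint random sets of
#' equal size, the total effect is estimated per trait in each arm, and the
#' two result tables are compared by z-score concordance.
#'
#' @param cohort Cohort tibble with exposure `A` and the subgroup flag among
#'   cases.
#' @param trait_specs As in [run_screen()].
#' @param config A [screen_config()].
#' @param flag Name of the binary subgroup flag column (1 = flagged case).
#' @param confounders Confounder columns.
#' @param seed Seed for the subsampling and control partition.
#' @return List of class `subgroup_comparison`: per-arm `trait_results`
#'   (`flagged`, `unflagged`), the `concordance` object, per-arm significant
#'   counts, and the arm sample sizes.
#' @export
pem_split_comparison <- function(cohort, trait_specs, config = screen_config(),
                                 flag = "pem_flag",
                                 confounders = c("age", "sex"), seed = 1L) {
  if (!flag %in% names(cohort)) {
    abort(paste0("unknown subgroup flag column: ", flag),
          class = "mediscreen_input_error")
  }
  cases <- cohort[cohort$A == 1, , drop = FALSE]
  controls <- cohort[cohort$A == 0, , drop = FALSE]
  flagged <- cases[!is.na(cases[[flag]]) & cases[[flag]] == 1, , drop = FALSE]
  unflagged <- cases[!is.na(cases[[flag]]) & cases[[flag]] == 0, , drop = FALSE]
  if (nrow(flagged) == 0 || nrow(unflagged) == 0) {
    abort("both case subgroups must be non-empty",
          class = "mediscreen_input_error")
  }
  if (nrow(controls) < 2) {
    abort("need at least 2 controls to form disjoint control sets",
          class = "mediscreen_input_error")
  }
  n_arm <- min(nrow(flagged), nrow(unflagged))

  with_rng(seed, function() {
    if (nrow(flagged) > n_arm) {
      flagged <- flagged[sample.int(nrow(flagged), n_arm), , drop = FALSE]
    }
    if (nrow(unflagged) > n_arm) {
      unflagged <- unflagged[sample.int(nrow(unflagged), n_arm), , drop = FALSE]
    }
    perm <- sample.int(nrow(controls))
    half <- floor(nrow(controls) / 2)
    controls_1 <- controls[perm[seq_len(half)], , drop = FALSE]
    controls_2 <- controls[perm[half + seq_len(half)], , drop = FALSE]

    run_arm <- function(arm_cases, arm_controls) {
      run_screen(dplyr::bind_rows(arm_cases, arm_controls), trait_specs,
                 mediators = "none", strata = "combined", estimands = "TE",
                 config = config, confounders = confounders)
    }
    res_flagged <- run_arm(flagged, controls_1)
    res_unflagged <- run_arm(unflagged, controls_2)

    structure(
      list(
        flagged = res_flagged, unflagged = res_unflagged,
        concordance = zscore_concordance(res_flagged, res_unflagged,
                                         estimand = "TE",
                                         labels = c("flagged", "unflagged")),
        n_significant = c(flagged = sum(res_flagged$significant),
                          unflagged = sum(res_unflagged$significant)),
        n_arm = n_arm,
        n_controls_per_arm = half,
        control_ids = list(arm1 = controls_1$subject_id,
                           arm2 = controls_2$subject_id)
      ),
      class = "subgroup_comparison"
    )
  })
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf(
    "<subgroup_comparison> %d cases per arm, %d controls per arm\n",
    x$n_arm, x$n_controls_per_arm
  ))
  cat(sprintf("  significant traits: flagged %d, unflagged %d\n",
              x$n_significant["flagged"], x$n_significant["unflagged"]))
  print(x$concordance)
  invisible(x)
}

#' Sensitivity of z-scores to case/control definition stringency
#'
#' Runs the total-effect screen on each cohort variant (e.g. with and
#' without a health-rating restriction in the case/control definitions) and
#' pairs per-trait z-scores across variants, reporting the Pearson
#' correlation of each pair of variants.
#'
#' @param cohort_variants Named list of cohort tibbles sharing the trait
#'   columns.
#' @param trait_specs As in [run_screen()].
#' @param config A [screen_config()].
#' @param confounders Confounder columns.
#' @param estimand `"TE"` or `"NDE"` (NDE requires a `mediator`).
#' @param mediator Mediator column for `estimand = "NDE"`.
#' @return List of class `stringency_sensitivity`: `z_table` (wide tibble of
#'   per-trait z-scores, one column per variant) and `correlations` (tibble
#'   of all variant pairs with Pearson `r` and `p`).
#' @export
stringency_sensitivity <- function(cohort_variants, trait_specs,
                                   config = screen_config(),
                                   confounders = c("age", "sex"),
                                   estimand = c("TE", "NDE"),
                                   mediator = "activity") {
  estimand <- match.arg(estimand)
  if (length(cohort_variants) < 2 || is.null(names(cohort_variants))) {
    abort("need a named list of at least 2 cohort variants",
          class = "mediscreen_input_error")
  }
  results <- lapply(cohort_variants, function(ch) {
    run_screen(ch, trait_specs,
               mediators = if (estimand == "TE") "none" else mediator,
               strata = "combined", estimands = estimand, config = config,
               confounders = confounders)
  })
  trait_sets <- lapply(results, function(r) sort(unique(r$trait)))
  if (!all(vapply(trait_sets, identical, logical(1), trait_sets[[1]]))) {
    abort("cohort variants yield mismatched trait sets",
          class = "mediscreen_input_error")
  }
  z_cols <- lapply(results, function(r) {
    dplyr::select(dplyr::filter(r, .data$estimand == !!estimand), "trait", "z")
  })
  z_table <- purrr::reduce(
    purrr::imap(z_cols, ~ stats::setNames(.x, c("trait", .y))),
    dplyr::inner_join, by = "trait"
  )
  nms <- names(cohort_variants)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  correlations <- dplyr::bind_rows(lapply(pairs, function(pr) {
    ct <- cor.test(z_table[[pr[1]]], z_table[[pr[2]]])
    tibble::tibble(variant_a = pr[1], variant_b = pr[2],
                   pearson_r = unname(ct$estimate), p.value = ct$p.value)
  }))
  structure(list(z_table = z_table, correlations = correlations,
                 results = results, estimand = estimand),
            class = "stringency_sensitivity")
}

#' @export
print.stringency_sensitivity <- function(x, ...) {
  cat(sprintf("<stringency_sensitivity> %s z-scores across %d variants\n",
              x$estimand, ncol(x$z_table) - 1))
  print(x$correlations)
  invisible(x)
}
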
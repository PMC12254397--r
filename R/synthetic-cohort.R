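#' Specify the structural equation model behind a synthetic cohort
#'
#' Encodes the generative model used to emulate a biobank-style mediation
#' cohort: a binary exposure `A` confounded by age and sex, a non-negative
#' continuous activity mediator `M` shifted by exposure, and many continuous
#' trait outcomes `Y_t` depending on exposure, mediator and confounders.
#' The structural equations are
#' \deqn{A \sim \mathrm{Bernoulli}(\mathrm{expit}(\gamma_0 + \gamma_{age} age
#'   + \gamma_{sex} sex))}
#' \deqn{M = \alpha_0 + \alpha_A A + \alpha_{age} age + \alpha_{sex} sex +
#'   \epsilon_M, \quad \epsilon_M \sim N(0, \sigma_M^2)}
#' \deqn{Y_t = \beta_0 + \beta_A A + \beta_M M + \beta_{age} age +
#'   \beta_{sex} sex + \epsilon_Y, \quad \epsilon_Y \sim N(0, \sigma_Y^2)}
#' with the observed mediator floored at zero (activity durations are
#' non-negative). The flooring is applied to observed data only; closed-form
#' effect truths are computed from the unfloored linear system (see
#' [closed_form_effects()]).
#'
#' Defaults mirror a large biobank case/control design: strong exposure
#' imbalance (1455 expected cases against 131,303 controls), recruitment ages
#' uniform on 40--69 years, 73% female, an activity mediator averaging about
#' 55 min/day in controls and 44 min/day in cases, and 20 traits whose total
#' effects span standardised shifts (Cohen's d) of 0.2--0.5. By default no
#' trait loads on the mediator (`M` coefficients zero), so true indirect
#' effects are null -- the regime in which direct effects dominate.
#'
#' @param n_cases,n_controls Expected numbers of exposed and unexposed
#'   subjects. The exposure is drawn from the logistic model above with the
#'   intercept calibrated so that the expected case count equals `n_cases`;
#'   realised counts vary binomially.
#' @param gamma Named numeric vector with elements `age` and `sex`: the
#'   exposure model's confounder coefficients. An `intercept` element may be
#'   supplied; if absent it is calibrated to the target case fraction.
#' @param alpha Named numeric vector with elements `intercept`, `A`, `age`,
#'   `sex`: the mediator model coefficients (minutes/day scale by default).
#' @param sigma_m Mediator noise standard deviation (> 0).
#' @param beta Data frame with one row per trait and columns `trait`
#'   (character), `intercept`, `A`, `M`, `age`, `sex`, `sigma` (> 0): the
#'   outcome model per trait. `NULL` builds the 20-trait default described
#'   above.
#' @param age_range Length-2 numeric, uniform age bounds in years.
#' @param sex_prevalence Probability that `sex == 1` (coded 1 = female).
#' @param missing_mediator,missing_trait MCAR missingness rates applied to
#'   the mediator and to each trait column at generation time.
#' @param special_code_rate Fraction of mediator responses replaced by a
#'   special non-response code (questionnaire "do not know" / "prefer not to
#'   answer" analogues).
#' @param special_codes Numeric sentinel values used for special mediator
#'   responses; must be disjoint from valid (non-negative) mediator values.
#' @param pem_rate Probability that a case carries the post-exertional
#'   malaise subgroup flag (`pem_flag`); controls are always 0.
#' @param floor_mediator Floor observed mediator values at zero?
#' @param n_extra_mediators Number of additional activity mediators to
#'   generate (same model as the primary, independent noise). Extra mediators
#'   do not enter the outcome model, so their true indirect effects are zero;
#'   they exist to exercise multi-mediator screening.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return An object of class `sem_config`.
#' @seealso [generate_cohort()], [closed_form_effects()]
#' @export
sem_config <- function(n_cases = 1455,
                       n_controls = 131303,
                       gamma = c(age = 0.01, sex = 0.7),
                       alpha = c(intercept = 65.9, A = -11.3,
                                 age = -0.2, sex = 0.5),
                       sigma_m = 20,
                       beta = NULL,
                       age_range = c(40, 69),
                       sex_prevalence = 0.73,
                       missing_mediator = 0.05,
                       missing_trait = 0.02,
                       special_code_rate = 0.01,
                       special_codes = c(-1, -3),
                       pem_rate = 0.55,
                       floor_mediator = TRUE,
                       n_extra_mediators = 0,
                       seed = 1L) {
  if (is.null(beta)) beta <- default_trait_beta()
  beta <- tibble::as_tibble(beta)
  cfg <- structure(
    list(
      n_cases = n_cases, n_controls = n_controls,
      gamma = gamma, alpha = alpha, sigma_m = sigma_m, beta = beta,
      age_range = age_range, sex_prevalence = sex_prevalence,
      missing_mediator = missing_mediator, missing_trait = missing_trait,
      special_code_rate = special_code_rate, special_codes = special_codes,
      pem_rate = pem_rate, floor_mediator = floor_mediator,
      n_extra_mediators = n_extra_mediators,
      seed = as.integer(seed)
    ),
    class = "sem_config"
  )
  validate_sem_config(cfg)
}

# 20 default traits with alternating-sign total effects whose standardised
# magnitudes span 0.2-0.5 (sigma_Y = 1, so beta_A is approximately Cohen's d).
default_trait_beta <- function(n_traits = 20) {
  d <- seq(0.2, 0.5, length.out = n_traits)
  sgn <- rep(c(1, -1), length.out = n_traits)
  tibble::tibble(
    trait = sprintf("trait_%02d", seq_len(n_traits)),
    intercept = 0,
    A = sgn * d,
    M = 0,
    age = 0.005,
    sex = 0.1,
    sigma = 1
  )
}

validate_sem_config <- function(cfg) {
  stopifnot(inherits(cfg, "sem_config"))
  if (cfg$n_cases + cfg$n_controls < 2) {
    abort("cohort must contain at least 2 subjects", class = "mediscreen_config_error")
  }
  if (cfg$sigma_m <= 0) {
    abort("sigma_m must be > 0", class = "mediscreen_config_error")
  }
  need <- c("trait", "intercept", "A", "M", "age", "sex", "sigma")
  missing_cols <- setdiff(need, names(cfg$beta))
  if (length(missing_cols)) {
    abort(paste0("beta is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "mediscreen_config_error")
  }
  if (any(cfg$beta$sigma <= 0)) {
    abort("all trait sigmas must be > 0", class = "mediscreen_config_error")
  }
  if (anyDuplicated(cfg$beta$trait)) {
    abort("trait names must be unique", class = "mediscreen_config_error")
  }
  probs <- c(cfg$sex_prevalence, cfg$missing_mediator, cfg$missing_trait,
             cfg$special_code_rate, cfg$pem_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "mediscreen_config_error")
  }
  if (any(cfg$special_codes >= 0)) {
    abort("special mediator codes must be negative so they are disjoint from valid values",
          class = "mediscreen_config_error")
  }
  cfg
}

#' @export
print.sem_config <- function(x, ...) {
  cat("<sem_config>\n")
  cat(sprintf("  expected cases/controls: %d / %d\n", x$n_cases, x$n_controls))
  cat(sprintf("  traits: %d; mediators: %d; seed: %d\n",
              nrow(x$beta), 1L + x$n_extra_mediators, x$seed))
  invisible(x)
}

# Exposure-model intercept calibrated so that E[A] matches the target case
# fraction for the configured age/sex distribution (population calibration,
# solved by monotone root finding on the logit scale).
calibrate_gamma0 <- function(cfg) {
  if ("intercept" %in% names(cfg$gamma)) return(unname(cfg$gamma["intercept"]))
  target <- cfg$n_cases / (cfg$n_cases + cfg$n_controls)
  # quadrature over age (uniform) and sex (Bernoulli)
  ages <- seq(cfg$age_range[1], cfg$age_range[2], length.out = 201)
  lin <- c(outer(cfg$gamma["age"] * ages, cfg$gamma["sex"] * c(0, 1), "+"))
  wts <- rep(c(1 - cfg$sex_prevalence, cfg$sex_prevalence), each = length(ages)) /
    length(ages)
  f <- function(g0) sum(wts * expit(g0 + lin)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

mediator_names <- function(cfg) {
  c("activity",
    if (cfg$n_extra_mediators > 0) {
      sprintf("activity_%d", seq_len(cfg$n_extra_mediators) + 1L)
    })
}

#' Generate a synthetic mediation cohort with known true effects
#'
#' Draws a cohort from the structural equation model in a [sem_config()] and
#' returns it together with the analytically known total, natural direct and
#' natural indirect effect of the exposure on every trait. Generation is a
#' pure function of the config (including its seed): identical configs give
#' byte-identical tables.
#'
#' @param config A [sem_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{cohort}{tibble with columns `subject_id`, `age`, `sex`, `A`,
#'       `pem_flag`, the mediator column(s) (`activity`, ...), and one column
#'       per trait. Mediator values may be special negative response codes;
#'       mediator and trait values may be `NA`.}
#'     \item{truth}{tibble with columns `trait`, `TE`, `NDE`, `NIE` from
#'       [closed_form_effects()]; `TE = NDE + NIE` exactly.}
#'   }
#' @examples
#' sim <- generate_cohort(sem_config(n_cases = 50, n_controls = 450, seed = 7))
#' dplyr::count(sim$cohort, A)
#' sim$truth
#' @export
generate_cohort <- function(config) {
  validate_sem_config(config)
  n <- config$n_cases + config$n_controls
  if (n < 2) abort("empty cohort", class = "mediscreen_config_error")
  g0 <- calibrate_gamma0(config)

  with_rng(config$seed, function() {
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- rbinom(n, 1, config$sex_prevalence)
    p_a <- expit(g0 + config$gamma["age"] * age + config$gamma["sex"] * sex)
    A <- rbinom(n, 1, p_a)

    med_mean <- config$alpha["intercept"] + config$alpha["A"] * A +
      config$alpha["age"] * age + config$alpha["sex"] * sex
    meds <- lapply(mediator_names(config), function(nm) {
      m <- unname(med_mean) + rnorm(n, 0, config$sigma_m)
      if (config$floor_mediator) m <- pmax(m, 0)
      m
    })
    names(meds) <- mediator_names(config)

    M1 <- meds[[1]]
    traits <- lapply(seq_len(nrow(config$beta)), function(t) {
      b <- config$beta[t, ]
      b$intercept + b$A * A + b$M * M1 + b$age * age + b$sex * sex +
        rnorm(n, 0, b$sigma)
    })
    names(traits) <- config$beta$trait

    pem <- ifelse(A == 1, rbinom(n, 1, config$pem_rate), 0L)

    cohort <- tibble::tibble(
      subject_id = sprintf("S%07d", seq_len(n)),
      age = age, sex = sex, A = A, pem_flag = as.integer(pem)
    )
    for (nm in names(meds)) cohort[[nm]] <- meds[[nm]]
    for (nm in names(traits)) cohort[[nm]] <- traits[[nm]]

    # special non-response codes on mediators, then MCAR missingness
    if (config$special_code_rate > 0) {
      for (nm in names(meds)) {
        hit <- runif(n) < config$special_code_rate
        if (any(hit)) {
          cohort[[nm]][hit] <- sample(config$special_codes, sum(hit), replace = TRUE)
        }
      }
    }
    rates <- c(
      setNames(rep(config$missing_mediator, length(meds)), names(meds)),
      setNames(rep(config$missing_trait, length(traits)), names(traits))
    )
    rates <- rates[rates > 0]
    if (length(rates)) {
      for (nm in names(rates)) {
        cohort[[nm]][runif(n) < rates[[nm]]] <- NA_real_
      }
    }

    structure(
      list(cohort = cohort, truth = closed_form_effects(config)),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d cases), %d traits\n",
              nrow(x$cohort), sum(x$cohort$A), nrow(x$truth)))
  invisible(x)
}

#' True total, direct and indirect effects implied by a structural model
#'
#' For the linear structural equation model of [sem_config()] (ignoring the
#' non-negativity floor on the mediator), the counterfactual means have closed
#' forms and the effects reduce to
#' \deqn{NDE = \beta_A, \qquad NIE = \beta_M \alpha_A, \qquad
#'   TE = \beta_A + \beta_M \alpha_A,}
#' per trait, so `TE = NDE + NIE` holds exactly. When the floor (or any other
#' nonlinearity) must be honoured, `method = "monte_carlo"` simulates the
#' counterfactual outcomes \eqn{Y(1, M(1))}, \eqn{Y(1, M(0))}, \eqn{Y(0, M(0))}
#' directly from the structural equations and differences their means; the
#' result is flagged via the `method` attribute.
#'
#' @param config A [sem_config()].
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @param n_mc Monte-Carlo sample size for `method = "monte_carlo"`.
#' @param mc_seed Seed for the Monte-Carlo draw (defaults to the config seed).
#' @return Tibble with columns `trait`, `TE`, `NDE`, `NIE`; attribute
#'   `method` records how the truth was computed.
#' @export
closed_form_effects <- function(config, method = c("closed_form", "monte_carlo"),
                                n_mc = 1e6, mc_seed = NULL) {
  validate_sem_config(config)
  method <- match.arg(method)
  if (method == "closed_form") {
    out <- tibble::tibble(
      trait = config$beta$trait,
      NDE = config$beta$A,
      NIE = config$beta$M * unname(config$alpha["A"]),
      TE = .data$NDE + .data$NIE
    ) |>
      dplyr::select("trait", "TE", "NDE", "NIE")
    attr(out, "method") <- "closed_form"
    return(out)
  }

  # Monte-Carlo counterfactual truth: honours the mediator floor.
  seed <- mc_seed %||% config$seed
  with_rng(seed, function() {
    age <- runif(n_mc, config$age_range[1], config$age_range[2])
    sex <- rbinom(n_mc, 1, config$sex_prevalence)
    base <- config$alpha["intercept"] + config$alpha["age"] * age +
      config$alpha["sex"] * sex
    eps_m <- rnorm(n_mc, 0, config$sigma_m)
    m0 <- unname(base) + eps_m
    m1 <- unname(base + config$alpha["A"]) + eps_m
    if (config$floor_mediator) {
      m0 <- pmax(m0, 0)
      m1 <- pmax(m1, 0)
    }
    rows <- lapply(seq_len(nrow(config$beta)), function(t) {
      b <- config$beta[t, ]
      # shared noise cancels in mean differences; omit eps_Y
      y_mean <- function(a, m) b$intercept + b$A * a + b$M * m +
        b$age * age + b$sex * sex
      psi11 <- mean(y_mean(1, m1))
      psi10 <- mean(y_mean(1, m0))
      psi00 <- mean(y_mean(0, m0))
      tibble::tibble(trait = b$trait, TE = psi11 - psi00,
                     NDE = psi10 - psi00, NIE = psi11 - psi10)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "method") <- "monte_carlo"
    out
  })
}

#' Inject missing-completely-at-random values into a cohort table
#'
#' Masks a given fraction of each requested column with `NA`. The exposure
#' column `A` (and `subject_id`) may never be masked.
#'
#' @param cohort A cohort tibble.
#' @param rates Named numeric vector: column name -> missingness rate in
#'   `[0, 1]`.
#' @param mechanism Only `"MCAR"` is supported.
#' @param seed Integer seed.
#' @return The cohort with values masked.
#' @export
inject_missingness <- function(cohort, rates, mechanism = "MCAR", seed = 1L) {
  mechanism <- match.arg(mechanism, "MCAR")
  if (any(rates < 0 | rates > 1)) {
    abort("missingness rates must lie in [0, 1]", class = "mediscreen_config_error")
  }
  bad <- intersect(names(rates), c("A", "subject_id"))
  if (length(bad)) {
    abort(paste0("columns may not be masked: ", paste(bad, collapse = ", ")),
          class = "mediscreen_config_error")
  }
  missing_cols <- setdiff(names(rates), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("unknown columns: ", paste(missing_cols, collapse = ", ")),
          class = "mediscreen_config_error")
  }
  with_rng(seed, function() {
    for (nm in names(rates)) {
      if (rates[[nm]] > 0) {
        cohort[[nm]][runif(nrow(cohort)) < rates[[nm]]] <- NA
      }
    }
    cohort
  })
}
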
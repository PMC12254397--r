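# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: effects are simulated or enumerated
# directly from first principles.

# Brute-force counterfactual simulator for the linear mediator/outcome SEM.
# Draws W, the two counterfactual mediators M(0)/M(1) with shared noise, and
# differences the counterfactual outcome means. Independent of
# closed_form_effects().
oracle_counterfactual_truth <- function(config, n = 1e6, seed = 99) {
  set.seed(seed)
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, config$sex_prevalence)
  base <- config$alpha[["intercept"]] + config$alpha[["age"]] * age +
    config$alpha[["sex"]] * sex
  eps <- rnorm(n, 0, config$sigma_m)
  m0 <- base + eps
  m1 <- base + config$alpha[["A"]] + eps
  if (config$floor_mediator) {
    m0 <- pmax(m0, 0)
    m1 <- pmax(m1, 0)
  }
  do.call(rbind, lapply(seq_len(nrow(config$beta)), function(t) {
    b <- config$beta[t, ]
    ym <- function(a, m) b$intercept + b$A * a + b$M * m + b$age * age +
      b$sex * sex
    y11 <- ym(1, m1); y10 <- ym(1, m0); y00 <- ym(0, m0)
    data.frame(
      trait = b$trait,
      TE = mean(y11 - y00), NDE = mean(y10 - y00), NIE = mean(y11 - y10),
      se_TE = sd(y11 - y00) / sqrt(n),
      se_NDE = sd(y10 - y00) / sqrt(n),
      se_NIE = sd(y11 - y10) / sqrt(n)
    )
  }))
}

# Brute-force Benjamini-Hochberg step-up: literal translation of the
# definition p_adj(i) = min_{j >= i} m p(j) / j at sorted positions.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * sorted[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive g-computation over the cells of an all-binary (W, A, M, Y)
# table: psi(a, a') = sum_w sum_m E[Y | a, m, w] P(m | a', w) P(w).
oracle_gcomp_psi <- function(dat, a, ap) {
  total <- 0
  for (w in 0:1) {
    pw <- mean(dat$W == w)
    for (m in 0:1) {
      ey <- mean(dat$Y[dat$A == a & dat$M == m & dat$W == w])
      pm <- mean(dat$M[dat$A == ap & dat$W == w] == m)
      total <- total + ey * pm * pw
    }
  }
  total
}

oracle_gcomp_te <- function(dat) {
  total <- 0
  for (w in 0:1) {
    pw <- mean(dat$W == w)
    total <- total +
      (mean(dat$Y[dat$A == 1 & dat$W == w]) -
         mean(dat$Y[dat$A == 0 & dat$W == w])) * pw
  }
  total
}

# All-binary cohort whose every (A, M, W) cell is populated; used for the
# saturated-nuisance oracle checks.
make_binary_cohort <- function(n = 500, seed = 11) {
  set.seed(seed)
  repeat {
    W <- rbinom(n, 1, 0.5)
    A <- rbinom(n, 1, plogis(-0.4 + 0.8 * W))
    M <- rbinom(n, 1, plogis(-0.2 + 0.9 * A + 0.5 * W))
    Y <- rbinom(n, 1, plogis(-0.5 + 0.7 * A + 0.6 * M + 0.4 * W))
    dat <- data.frame(W = W, A = A, M = M, Y = Y)
    cells <- with(dat, table(A, M, W))
    if (all(cells > 0)) return(tibble::as_tibble(dat))
    seed <- seed + 1
    set.seed(seed)
  }
}

# Small clean SEM config for estimation tests: no missingness or special
# codes, flooring negligible at these coefficient scales.
clean_sem <- function(n_cases, n_controls, beta, seed,
                      alpha = c(intercept = 65.9, A = -11.3, age = -0.2,
                                sex = 0.5),
                      sigma_m = 20,
                      gamma = c(age = 0.01, sex = 0.7)) {
  sem_config(
    n_cases = n_cases, n_controls = n_controls, beta = beta, seed = seed,
    alpha = alpha, sigma_m = sigma_m, gamma = gamma,
    missing_mediator = 0, missing_trait = 0, special_code_rate = 0
  )
}

one_trait_beta <- function(bA = 0.5, bM = 0.02, sigma = 1) {
  data.frame(trait = "t1", intercept = 0, A = bA, M = bM, age = 0.005,
             sex = 0.1, sigma = sigma)
}
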
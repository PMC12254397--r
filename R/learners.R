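#' Base learners for nuisance estimation
#'
#' A learner is a lightweight fit/predict pair used as a component of the
#' cross-validated stacked ensemble ([fit_superlearner()]). Each constructor
#' returns a `learner_spec` with a `fit(x, y, family)` function returning an
#' opaque model object and a `predict(model, x)` function returning
#' conditional-mean estimates (probabilities in `[0, 1]` for the binary
#' family). Learners must produce finite predictions; a learner that errors
#' during ensemble fitting is dropped with a warning rather than aborting a
#' screen of thousands of traits.
#'
#' Available learners:
#' \describe{
#'   \item{`lrn_mean()`}{marginal mean / prevalence; the "null" benchmark.}
#'   \item{`lrn_glm()`}{generalised linear model with main terms.}
#'   \item{`lrn_glm_interaction()`}{GLM with main terms and all two-way
#'     interactions.}
#'   \item{`lrn_glmnet()`}{L1-penalised (LASSO) GLM with internal
#'     cross-validated lambda selection (default tenfold).}
#'   \item{`lrn_xgboost()`}{extreme gradient boosting (requires the
#'     `xgboost` package).}
#'   \item{`lrn_gam()`}{adaptive smoothing-spline regression via
#'     `mgcv::gam()`, the flexible nonlinear archetype (requires `mgcv`).}
#'   \item{`lrn_saturated()`}{empirical conditional means per distinct
#'     covariate pattern; on all-discrete data this is the nonparametric
#'     maximum-likelihood fit, used for exact oracle checks.}
#' }
#'
#' @param name Learner label used in fit summaries and logs.
#' @return A `learner_spec` object.
#' @name learners
NULL

new_learner <- function(name, fit, predict, hyper = list()) {
  structure(list(name = name, fit = fit, predict = predict, hyper = hyper),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec: %s>\n", x$name))
  invisible(x)
}

as_num_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  m
}

#' @rdname learners
#' @export
lrn_mean <- function(name = "mean") {
  new_learner(
    name,
    fit = function(x, y, family) list(mu = mean(y)),
    predict = function(model, x) rep(model$mu, nrow(as_num_matrix(x)))
  )
}

# IRLS on an explicit design matrix; much faster than the formula interface.
glm_design_fit <- function(xm, y, family) {
  xm1 <- cbind(`(Intercept)` = 1, xm)
  fam <- if (family == "binary") binomial() else gaussian()
  fit <- suppressWarnings(stats::glm.fit(xm1, y, family = fam))
  list(coef = coef(fit), family = family)
}

glm_design_predict <- function(model, xm) {
  xm1 <- cbind(1, xm)
  b <- model$coef
  b[is.na(b)] <- 0
  eta <- drop(xm1 %*% b)
  if (model$family == "binary") expit(eta) else eta
}

#' @rdname learners
#' @export
lrn_glm <- function(name = "glm") {
  new_learner(
    name,
    fit = function(x, y, family) glm_design_fit(as_num_matrix(x), y, family),
    predict = function(model, x) glm_design_predict(model, as_num_matrix(x))
  )
}

interaction_expand <- function(xm) {
  p <- ncol(xm)
  if (p < 2) return(xm)
  pairs <- utils::combn(p, 2)
  inter <- apply(pairs, 2, function(ij) xm[, ij[1]] * xm[, ij[2]])
  inter <- matrix(inter, nrow = nrow(xm))
  colnames(inter) <- apply(pairs, 2, function(ij) {
    paste(colnames(xm)[ij], collapse = ":")
  })
  cbind(xm, inter)
}

#' @rdname learners
#' @export
lrn_glm_interaction <- function(name = "glm_interaction") {
  new_learner(
    name,
    fit = function(x, y, family) {
      glm_design_fit(interaction_expand(as_num_matrix(x)), y, family)
    },
    predict = function(model, x) {
      glm_design_predict(model, interaction_expand(as_num_matrix(x)))
    }
  )
}

#' @rdname learners
#' @param alpha Elastic-net mixing parameter (1 = LASSO).
#' @param nfolds Internal cross-validation folds for lambda selection.
#' @export
lrn_glmnet <- function(alpha = 1, nfolds = 10, name = "glmnet") {
  new_learner(
    name,
    fit = function(x, y, family) {
      xm <- as_num_matrix(x)
      # glmnet needs >= 2 predictor columns; pad with a zero column if needed
      if (ncol(xm) < 2) xm <- cbind(xm, .pad = 0)
      fam <- if (family == "binary") "binomial" else "gaussian"
      fit <- glmnet::cv.glmnet(xm, y, alpha = alpha, nfolds = nfolds,
                               family = fam)
      list(fit = fit, family = family, pad = ncol(as_num_matrix(x)) < 2)
    },
    predict = function(model, x) {
      xm <- as_num_matrix(x)
      if (model$pad) xm <- cbind(xm, .pad = 0)
      drop(predict(model$fit, newx = xm, s = "lambda.min", type = "response"))
    },
    hyper = list(alpha = alpha, nfolds = nfolds)
  )
}

#' @rdname learners
#' @param nrounds Boosting rounds; other xgboost parameters are left at the
#'   implementation defaults.
#' @export
lrn_xgboost <- function(nrounds = 50, name = "xgboost") {
  new_learner(
    name,
    fit = function(x, y, family) {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        abort("lrn_xgboost requires the 'xgboost' package")
      }
      yy <- if (family == "binary") factor(y, levels = c(0, 1)) else y
      fit <- xgboost::xgboost(as_num_matrix(x), yy, nrounds = nrounds,
                              verbosity = 0, nthreads = 1)
      list(fit = fit, family = family)
    },
    predict = function(model, x) {
      p <- predict(model$fit, as_num_matrix(x), type = "response")
      if (model$family == "binary" && is.matrix(p)) p <- p[, 2]
      as.numeric(p)
    },
    hyper = list(nrounds = nrounds)
  )
}

#' @rdname learners
#' @export
lrn_gam <- function(name = "gam") {
  new_learner(
    name,
    fit = function(x, y, family) {
      if (!requireNamespace("mgcv", quietly = TRUE)) {
        abort("lrn_gam requires the 'mgcv' package")
      }
      xm <- as_num_matrix(x)
      df <- as.data.frame(xm)
      names(df) <- paste0("x", seq_len(ncol(df)))
      df$.y <- y
      terms <- vapply(seq_len(ncol(xm)), function(j) {
        u <- length(unique(xm[, j]))
        if (u >= 10) {
          sprintf("s(x%d, k = %d)", j, min(10L, u - 1L))
        } else {
          sprintf("x%d", j)
        }
      }, character(1))
      fam <- if (family == "binary") binomial() else gaussian()
      fit <- mgcv::gam(as.formula(paste(".y ~", paste(terms, collapse = " + "))),
                       family = fam, data = df)
      list(fit = fit, p = ncol(xm))
    },
    predict = function(model, x) {
      df <- as.data.frame(as_num_matrix(x))
      names(df) <- paste0("x", seq_len(ncol(df)))
      as.numeric(predict(model$fit, newdata = df, type = "response"))
    }
  )
}

#' @rdname learners
#' @export
lrn_saturated <- function(name = "saturated") {
  new_learner(
    name,
    fit = function(x, y, family) {
      xm <- as_num_matrix(x)
      key <- apply(xm, 1, paste, collapse = "\r")
      means <- tapply(y, key, mean)
      list(means = means, fallback = mean(y))
    },
    predict = function(model, x) {
      xm <- as_num_matrix(x)
      key <- apply(xm, 1, paste, collapse = "\r")
      out <- unname(model$means[key])
      out[is.na(out)] <- model$fallback
      as.numeric(out)
    }
  )
}

#' Default learner libraries
#'
#' `default_learner_library()` returns the full stacking library (adaptive
#' splines via GAM, LASSO, GLM with two-way interactions, gradient boosting);
#' `fast_learner_library()` returns the single main-terms GLM used when a
#' lean, correctly-specified nuisance model suffices (e.g. large simulation
#' studies); it is also the "no Super Learner" baseline configuration when
#' set to the penalised GLM alone via `no_sl_library()`.
#'
#' @return List of `learner_spec` objects.
#' @export
default_learner_library <- function() {
  list(lrn_gam(), lrn_glmnet(), lrn_glm_interaction(), lrn_xgboost())
}

#' @rdname default_learner_library
#' @export
fast_learner_library <- function() {
  list(lrn_glm())
}

#' @rdname default_learner_library
#' @export
no_sl_library <- function() {
  list(lrn_glmnet())
}

#' Cross-validation fold assignment
#'
#' Assigns each of `n` rows to one of `K` folds. Without stratification, fold
#' sizes differ by at most one. With `stratify_labels`, each label's rows are
#' balanced across folds (per-label fold counts differ by at most one), the
#' construction recommended for rare binary outcomes. Deterministic given
#' `seed`.
#'
#' @param n Number of rows.
#' @param K Number of folds, `2 <= K <= n`.
#' @param stratify_labels Optional vector of length `n`; folds are balanced
#'   within each distinct label. A label with fewer rows than `K` triggers a
#'   warning (some folds will not see that label).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..K`.
#' @export
make_folds <- function(n, K, stratify_labels = NULL, seed = 1L) {
  if (K < 2 || K > n) {
    abort(sprintf("need 2 <= K <= n; got K = %d, n = %d", K, n),
          class = "mediscreen_config_error")
  }
  with_rng(seed, function() {
    if (is.null(stratify_labels)) {
      return(sample(rep(seq_len(K), length.out = n)))
    }
    stopifnot(length(stratify_labels) == n)
    folds <- integer(n)
    for (lev in unique(stratify_labels)) {
      idx <- which(stratify_labels == lev)
      if (length(idx) < K) {
        warn(sprintf(
          "stratum '%s' has %d rows, fewer than K = %d folds; folds will not all contain it",
          lev, length(idx), K
        ))
      }
      # random rotation keeps overall fold sizes near-balanced across strata
      start <- sample.int(K, 1)
      ids <- (start + seq_along(idx) - 2L) %% K + 1L
      folds[idx] <- sample(ids)
    }
    folds
  })
}
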
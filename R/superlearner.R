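#' Fit a cross-validated stacked ensemble (Super Learner)
#'
#' Fits every learner in `library` on `K`-fold training splits, collects
#' held-out predictions, and chooses convex meta-weights (non-negative,
#' summing to one) minimising the cross-validated squared-error risk over the
#' simplex. The simplex problem is solved exactly by active-set enumeration
#' (library sizes are small), so the ensemble's cross-validated risk never
#' exceeds that of the best single learner. Base learners are then refit on
#' the full data for prediction via [sl_predict()].
#'
#' For the binary family the learners model conditional probabilities and the
#' meta-step minimises the squared-error (Brier) risk on held-out
#' probabilities, so the recorded `cv_risks` are on the same criterion the
#' weights optimise.
#'
#' A learner that errors on any training split is dropped with a warning
#' (screening thousands of traits must not abort on one degenerate fit); if
#' every learner fails, fitting errors. With a single learner the meta-weight
#' is forced to 1 and no cross-validation pass is run.
#'
#' @param x Covariates: data frame or numeric matrix (no missing values).
#' @param y Response vector (0/1 for `family = "binary"`).
#' @param library List of `learner_spec` objects (see [learners]).
#' @param K Number of cross-validation folds.
#' @param family `"continuous"` or `"binary"`.
#' @param seed Integer seed for fold assignment.
#' @param stratify_cv For the binary family, balance folds on `y`?
#' @param clip_eps Probabilities are clipped to `[clip_eps, 1 - clip_eps]` at
#'   prediction time for the binary family.
#' @return An `sl_fit` with meta-`weights`, per-learner `cv_risks`,
#'   `ensemble_risk`, `folds`, and full-data base fits.
#' @export
fit_superlearner <- function(x, y, library = default_learner_library(),
                             K = 10, family = c("continuous", "binary"),
                             seed = 1L, stratify_cv = FALSE,
                             clip_eps = 0.001) {
  family <- match.arg(family)
  xm <- as_num_matrix(x)
  if (anyNA(xm) || anyNA(y)) {
    abort("x and y must not contain missing values",
          class = "mediscreen_input_error")
  }
  if (length(y) != nrow(xm)) abort("length(y) must equal nrow(x)")
  if (!length(library)) abort("learner library is empty")
  n <- length(y)
  names(library) <- vapply(library, `[[`, character(1), "name")

  fit_full <- function(lrn) tryCatch(lrn$fit(xm, y, family), error = identity)

  if (length(library) == 1) {
    full <- fit_full(library[[1]])
    if (inherits(full, "error")) {
      abort(paste0("the only learner failed: ", conditionMessage(full)))
    }
    return(new_sl_fit(
      library = library, weights = c(1), cv_risks = NA_real_,
      ensemble_risk = NA_real_, folds = rep(1L, n), family = family,
      full_fits = list(full), kept = 1L, feature_names = colnames(xm),
      clip_eps = clip_eps
    ))
  }

  folds <- make_folds(n, K,
                      stratify_labels = if (stratify_cv) y else NULL,
                      seed = seed)

  # held-out prediction matrix, one column per learner
  L <- length(library)
  Z <- matrix(NA_real_, n, L, dimnames = list(NULL, names(library)))
  failed <- logical(L)
  for (l in seq_len(L)) {
    lrn <- library[[l]]
    for (k in seq_len(K)) {
      test <- folds == k
      res <- tryCatch({
        m <- lrn$fit(xm[!test, , drop = FALSE], y[!test], family)
        p <- lrn$predict(m, xm[test, , drop = FALSE])
        stopifnot(length(p) == sum(test), all(is.finite(p)))
        p
      }, error = identity)
      if (inherits(res, "error") || inherits(res, "condition")) {
        failed[l] <- TRUE
        break
      }
      Z[test, l] <- res
    }
  }
  if (any(failed)) {
    warn(paste0("dropping failed learner(s): ",
                paste(names(library)[failed], collapse = ", ")))
  }
  if (all(failed)) abort("all learners failed during cross-validation")
  keep <- which(!failed)
  Zk <- Z[, keep, drop = FALSE]
  if (family == "binary") Zk <- pmin(pmax(Zk, 0), 1)

  cv_risks <- colMeans((y - Zk)^2)
  w <- simplex_ls(Zk, y)
  ensemble_risk <- mean((y - drop(Zk %*% w))^2)

  full_fits <- vector("list", length(keep))
  full_failed <- FALSE
  for (j in seq_along(keep)) {
    full <- fit_full(library[[keep[j]]])
    if (inherits(full, "error")) {
      # failed on full data despite CV success: zero it out and renormalise
      warn(paste0("learner '", names(library)[keep[j]],
                  "' failed on the full data; weight set to 0"))
      w[j] <- 0
      full_failed <- TRUE
    } else {
      full_fits[[j]] <- full
    }
  }
  if (sum(w) <= 0) abort("all weighted learners failed on the full data")
  if (full_failed) {
    w <- w / sum(w)
    ensemble_risk <- mean((y - drop(Zk %*% w))^2)
  }

  new_sl_fit(
    library = library, weights = w, cv_risks = cv_risks,
    ensemble_risk = ensemble_risk, folds = folds, family = family,
    full_fits = full_fits, kept = keep, feature_names = colnames(xm),
    clip_eps = clip_eps, check_domination = !full_failed
  )
}

new_sl_fit <- function(library, weights, cv_risks, ensemble_risk, folds,
                       family, full_fits, kept, feature_names, clip_eps,
                       check_domination = TRUE) {
  stopifnot(all(weights >= -1e-8), abs(sum(weights) - 1) < 1e-8)
  if (check_domination && !anyNA(cv_risks) && !is.na(ensemble_risk)) {
    stopifnot(ensemble_risk <= min(cv_risks) + 1e-8)
  }
  structure(
    list(
      library = library, weights = weights, cv_risks = cv_risks,
      ensemble_risk = ensemble_risk, folds = folds, family = family,
      full_fits = full_fits, kept = kept, feature_names = feature_names,
      clip_eps = clip_eps
    ),
    class = "sl_fit"
  )
}

# Exact min ||y - Zw||^2 over the probability simplex by enumerating active
# sets: for each non-empty support S solve the sum-to-one equality-constrained
# least squares via its KKT system and keep feasible (non-negative) solutions.
# Vertices are included, so the optimum never loses to a single learner.
# Subsets are visited smallest-first and in column order, so exact ties break
# toward earlier learners in the library.
simplex_ls <- function(Z, y) {
  L <- ncol(Z)
  if (L == 1) return(1)
  if (L > 14) abort("learner library too large for exact simplex stacking (max 14)")
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  best_w <- NULL
  best_risk <- Inf
  sizes <- seq_len(L)
  for (s in sizes) {
    for (S in utils::combn(L, s, simplify = FALSE)) {
      A <- rbind(cbind(2 * ZtZ[S, S, drop = FALSE], 1), c(rep(1, s), 0))
      b <- c(2 * Zty[S], 1)
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      wS <- sol[seq_len(s)]
      if (any(wS < -1e-10)) next
      wS <- pmax(wS, 0)
      wS <- wS / sum(wS)
      w <- numeric(L)
      w[S] <- wS
      risk <- mean((y - drop(Z %*% w))^2)
      if (risk < best_risk - 1e-12) {
        best_risk <- risk
        best_w <- w
      }
    }
  }
  if (is.null(best_w)) {
    # pathological collinearity everywhere: fall back to the best vertex
    risks <- colMeans((y - Z)^2)
    best_w <- numeric(L)
    best_w[which.min(risks)] <- 1
  }
  best_w
}

#' Predict from a fitted Super Learner
#'
#' Weighted combination of the full-data base-learner fits using the convex
#' meta-weights. Binary-family predictions are clipped to
#' `[clip_eps, 1 - clip_eps]` so downstream density-ratio terms stay finite.
#'
#' @param fit An `sl_fit` from [fit_superlearner()].
#' @param newdata Covariates with the training columns.
#' @return Numeric vector of predictions.
#' @export
sl_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "sl_fit"))
  xm <- as_num_matrix(newdata)
  if (!is.null(fit$feature_names) && !is.null(colnames(xm)) &&
      !identical(colnames(xm), fit$feature_names)) {
    if (!all(fit$feature_names %in% colnames(xm))) {
      abort(paste0("newdata is missing columns: ",
                   paste(setdiff(fit$feature_names, colnames(xm)), collapse = ", ")),
            class = "mediscreen_input_error")
    }
    xm <- xm[, fit$feature_names, drop = FALSE]
  }
  pred <- numeric(nrow(xm))
  for (j in seq_along(fit$kept)) {
    if (fit$weights[j] > 0) {
      lrn <- fit$library[[fit$kept[j]]]
      pred <- pred + fit$weights[j] * lrn$predict(fit$full_fits[[j]], xm)
    }
  }
  if (fit$family == "binary") {
    pred <- pmin(pmax(pred, fit$clip_eps), 1 - fit$clip_eps)
  }
  pred
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf("<sl_fit> family: %s, %d learner(s)\n", x$family,
              length(x$kept)))
  nm <- names(x$library)[x$kept]
  for (j in seq_along(x$kept)) {
    cat(sprintf("  %-18s weight %.3f  cv_risk %s\n", nm[j], x$weights[j],
                if (all(is.na(x$cv_risks))) "-" else format(x$cv_risks[j], digits = 4)))
  }
  invisible(x)
}

#' @describeIn fit_superlearner One row per retained learner with its
#'   meta-weight and cross-validated risk.
#' @param x An `sl_fit`.
#' @param ... Unused.
#' @method tidy sl_fit
#' @export
tidy.sl_fit <- function(x, ...) {
  tibble::tibble(
    learner = names(x$library)[x$kept],
    weight = as.numeric(x$weights),
    cv_risk = if (all(is.na(x$cv_risks))) NA_real_ else as.numeric(x$cv_risks)
  )
}

#' @describeIn fit_superlearner One-row summary (family, learner count,
#'   ensemble cross-validated risk).
#' @method glance sl_fit
#' @export
glance.sl_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_learners = length(x$kept),
    ensemble_cv_risk = x$ensemble_risk,
    min_learner_cv_risk = if (all(is.na(x$cv_risks))) NA_real_ else min(x$cv_risks)
  )
}
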
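#' Triglyceride-glucose (TyG) insulin-resistance index
#'
#' \deqn{TyG = \ln( TG[mg/dL] \times Glucose[mg/dL] / 2 ).}
#' Biobank assays commonly report mmol/L; those inputs are converted to
#' mg/dL before the formula (triglycerides x 88.57, glucose x 18.018), with
#' `convert = FALSE` available to apply the formula to mmol/L values
#' directly. Non-positive concentrations give a missing index for that
#' subject, which propagates to the complete-case filter downstream.
#'
#' @param triglycerides,glucose Numeric concentration vectors.
#' @param units Units of both inputs: `"mg/dL"` or `"mmol/L"`.
#' @param convert Convert mmol/L inputs to mg/dL before the formula?
#' @return Numeric vector of dimensionless TyG values.
#' @examples
#' compute_tyg(100, 100) # ln(5000) ~ 8.517
#' @export
compute_tyg <- function(triglycerides, glucose, units = c("mg/dL", "mmol/L"),
                        convert = TRUE) {
  units <- match.arg(units)
  tg <- triglycerides
  glu <- glucose
  if (units == "mmol/L" && convert) {
    tg <- tg * 88.57
    glu <- glu * 18.018
  }
  out <- ifelse(tg > 0 & glu > 0, log(tg * glu / 2), NA_real_)
  out[is.na(tg) | is.na(glu)] <- NA_real_
  out
}

#' Triglyceride to HDL-cholesterol ratio
#'
#' TG/HDL-C in consistent units (any common unit cancels). Zero or negative
#' HDL-C gives a missing ratio.
#'
#' @param triglycerides,hdl_c Numeric concentration vectors in the same
#'   units.
#' @return Numeric ratio vector.
#' @export
compute_tg_hdl_ratio <- function(triglycerides, hdl_c) {
  out <- ifelse(!is.na(hdl_c) & hdl_c > 0, triglycerides / hdl_c, NA_real_)
  out[is.na(triglycerides)] <- NA_real_
  out
}

#' Winsorize a numeric vector at quantile bounds
#'
#' Values below the `lower_fraction` quantile are set to that quantile;
#' symmetrically above `1 - upper_fraction`. Quantiles are inverse-ECDF
#' order statistics (R's type 1), computed on the non-missing values;
#' missing values are left untouched and output order is preserved. The
#' inverse-ECDF convention makes the operation exactly idempotent (the
#' clipped bound is itself the corresponding quantile of the clipped data),
#' which interpolated quantile definitions do not guarantee; it is also
#' monotone.
#'
#' @param values Numeric vector.
#' @param lower_fraction,upper_fraction Tail fractions in `[0, 0.5)`;
#'   `upper_fraction` defaults to `lower_fraction`.
#' @return Winsorized vector, same length and order.
#' @export
winsorize <- function(values, lower_fraction, upper_fraction = lower_fraction) {
  if (lower_fraction < 0 || lower_fraction >= 0.5 ||
      upper_fraction < 0 || upper_fraction >= 0.5) {
    abort("winsorization fractions must lie in [0, 0.5)",
          class = "mediscreen_config_error")
  }
  if (lower_fraction == 0 && upper_fraction == 0) return(values)
  ok <- !is.na(values)
  if (!any(ok)) return(values)
  lo <- quantile(values[ok], lower_fraction, type = 1, names = FALSE)
  hi <- quantile(values[ok], 1 - upper_fraction, type = 1, names = FALSE)
  out <- values
  out[ok] <- pmin(pmax(values[ok], lo), hi)
  out
}

#' Restrict a cohort to complete cases on required columns
#'
#' @param cohort Cohort tibble.
#' @param required_columns Columns that must be non-missing.
#' @return List with `cohort` (filtered), `n_removed`, and
#'   `removed_per_column` (named count of missing values per required column
#'   among the removed rows).
#' @export
complete_case_filter <- function(cohort, required_columns) {
  missing_cols <- setdiff(required_columns, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("unknown columns: ", paste(missing_cols, collapse = ", ")),
          class = "mediscreen_input_error")
  }
  keep <- complete.cases(cohort[required_columns])
  removed <- cohort[!keep, required_columns, drop = FALSE]
  per_col <- vapply(removed, function(v) sum(is.na(v)), integer(1))
  n_removed <- sum(!keep)
  if (n_removed == nrow(cohort)) {
    warn("complete-case filter removed every row")
  }
  list(cohort = cohort[keep, , drop = FALSE], n_removed = n_removed,
       removed_per_column = per_col)
}

#' Remove special mediator response codes
#'
#' Questionnaire mediators carry sentinel codes for non-responses ("do not
#' know" / "prefer not to answer" analogues, encoded as negative values
#' disjoint from valid non-negative durations). Rows whose mediator value is
#' in the code set are removed before any direct/indirect effect estimation;
#' total-effect analyses never apply this filter because they do not use the
#' mediator.
#'
#' @param cohort Cohort tibble.
#' @param mediator Mediator column name.
#' @param special_codes Numeric code set (must be disjoint from valid
#'   values; asserted).
#' @return List with `cohort` (filtered) and `n_removed`.
#' @export
mediator_response_filter <- function(cohort, mediator,
                                     special_codes = c(-1, -3)) {
  if (!mediator %in% names(cohort)) {
    abort(paste0("unknown mediator column: ", mediator),
          class = "mediscreen_input_error")
  }
  if (any(special_codes >= 0)) {
    abort("special codes must be negative (disjoint from valid mediator values)",
          class = "mediscreen_config_error")
  }
  m <- cohort[[mediator]]
  drop_row <- !is.na(m) & m %in% special_codes
  list(cohort = cohort[!drop_row, , drop = FALSE], n_removed = sum(drop_row))
}

#' Average repeated measurements to one value per subject
#'
#' Biobank replication cohorts record traits at multiple visits; analyses use
#' the per-subject arithmetic mean. For composite traits, compute the
#' composite per contemporaneous measurement first (components measured at
#' the same time), then average the composites -- not the other way round.
#'
#' @param long_table Long-format tibble with one row per measurement.
#' @param id_col Subject identifier column.
#' @param value_cols Measurement columns to average (default: all numeric
#'   columns except `id_col`).
#' @return Tibble with one row per subject and the per-subject means;
#'   subjects with no non-missing measurements of a column get `NA`.
#' @examples
#' long <- tibble::tibble(
#'   subject_id = c("s1", "s1", "s2"), tg = c(100, 120, 90),
#'   glucose = c(90, 110, 100)
#' )
#' long$tyg <- compute_tyg(long$tg, long$glucose)
#' average_repeated_measurements(long, value_cols = "tyg")
#' @export
average_repeated_measurements <- function(long_table, id_col = "subject_id",
                                          value_cols = NULL) {
  if (!id_col %in% names(long_table)) {
    abort(paste0("unknown id column: ", id_col),
          class = "mediscreen_input_error")
  }
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(long_table)[vapply(long_table, is.numeric,
                                                   logical(1))], id_col)
  }
  long_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_col))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(value_cols),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Cohen's d standardised mean difference
#'
#' `(mean(case) - mean(control)) / pooled SD`, with the pooled standard
#' deviation \eqn{\sqrt{((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)}}.
#' Missing values are dropped per group. A zero pooled SD gives `NA`.
#'
#' @param case_values,control_values Numeric vectors (>= 2 non-missing values
#'   each).
#' @return Dimensionless effect size.
#' @export
cohens_d <- function(case_values, control_values) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Welch's unequal-variance t test from summary statistics
#'
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with the Welch--Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return One-row tibble with `t`, `df`, `p`.
#' @examples
#' # male-cohort body-mass-index comparison from summary statistics
#' welch_t(27.96, 4.62, 386, 26.80, 3.58, 55572)
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) abort("standard deviations must be >= 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) abort("both groups have zero variance: t undefined")
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Declare a trait for screening
#'
#' A `trait_spec` names either a raw cohort column or a composite to be
#' computed from components before screening. Built-in composites: `"tyg"`
#' (needs components `triglycerides`, `glucose`) and `"tg_hdl"` (needs
#' `triglycerides`, `hdl_c`).
#'
#' @param name Output column / trait name.
#' @param kind `"raw"` or `"composite"`.
#' @param composite For composites, `"tyg"` or `"tg_hdl"`.
#' @param components Named character vector mapping formula arguments to
#'   cohort columns, e.g. `c(triglycerides = "tg", glucose = "glu")`.
#' @param units Units passed to the composite formula (TyG conversion).
#' @param winsor Winsorization fraction for this trait (0 = off; applied
#'   symmetrically unless overridden by the screen config).
#' @return A `trait_spec` object.
#' @export
trait_spec <- function(name, kind = c("raw", "composite"), composite = NULL,
                       components = NULL, units = "mg/dL", winsor = 0) {
  kind <- match.arg(kind)
  if (winsor < 0 || winsor >= 0.5) {
    abort("winsorization fraction must lie in [0, 0.5)",
          class = "mediscreen_config_error")
  }
  if (kind == "composite") {
    composite <- match.arg(composite, c("tyg", "tg_hdl"))
    need <- if (composite == "tyg") c("triglycerides", "glucose") else
      c("triglycerides", "hdl_c")
    if (is.null(components) || !all(need %in% names(components))) {
      abort(paste0("composite '", composite, "' needs components: ",
                   paste(need, collapse = ", ")),
            class = "mediscreen_config_error")
    }
  }
  structure(list(name = name, kind = kind, composite = composite,
                 components = components, units = units, winsor = winsor),
            class = "trait_spec")
}

# Materialise composite trait columns on the cohort; raw specs must already
# exist as columns. Composites are missing whenever any component is missing.
build_trait_columns <- function(cohort, trait_specs) {
  for (ts in trait_specs) {
    if (ts$kind == "raw") {
      if (!ts$name %in% names(cohort)) {
        abort(paste0("unknown trait column: ", ts$name),
              class = "mediscreen_input_error")
      }
    } else {
      comp <- ts$components
      missing_cols <- setdiff(unname(comp), names(cohort))
      if (length(missing_cols)) {
        abort(paste0("composite '", ts$name, "' components not in cohort: ",
                     paste(missing_cols, collapse = ", ")),
              class = "mediscreen_input_error")
      }
      cohort[[ts$name]] <- switch(
        ts$composite,
        tyg = compute_tyg(cohort[[comp[["triglycerides"]]]],
                          cohort[[comp[["glucose"]]]], units = ts$units),
        tg_hdl = compute_tg_hdl_ratio(cohort[[comp[["triglycerides"]]]],
                                      cohort[[comp[["hdl_c"]]]])
      )
    }
  }
  cohort
}

as_trait_specs <- function(trait_specs) {
  if (inherits(trait_specs, "trait_spec")) return(list(trait_specs))
  if (is.character(trait_specs)) {
    return(lapply(trait_specs, function(nm) trait_spec(nm)))
  }
  stopifnot(all(vapply(trait_specs, inherits, logical(1), "trait_spec")))
  trait_specs
}
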
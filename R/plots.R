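#' Scatter plot of paired z-scores between two analyses
#'
#' The standard concordance display: per-trait z-scores of one analysis
#' against another, coloured by joint FDR significance class, with the
#' identity line for reference.
#'
#' @param x A `zscore_concordance` object from [zscore_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_concordance <- function(x, ...) {
  stopifnot(inherits(x, "zscore_concordance"))
  ggplot2::ggplot(x$classes,
                  ggplot2::aes(x = .data$z_1, y = .data$z_2,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = paste0(x$labels[1], " z-score"),
      y = paste0(x$labels[2], " z-score"),
      colour = NULL,
      title = sprintf("%s concordance: Pearson r = %.2f (p = %.2g, %d traits)",
                      x$estimand, x$pearson_r, x$p, x$n_traits)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_concordance
#' @param object A `zscore_concordance` object.
#' @method autoplot zscore_concordance
#' @export
autoplot.zscore_concordance <- function(object, ...) plot_concordance(object, ...)

#' Forest plot of screening estimates
#'
#' Point estimates with 95% confidence intervals for one estimand, ordered by
#' effect size; by default only FDR-significant traits are shown (the usual
#' presentation for a biomarker screen).
#'
#' @param results A `trait_results` tibble from [run_screen()].
#' @param estimand Which estimand to display.
#' @param significant_only Show only FDR-significant rows?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_effects <- function(results, estimand = "NDE", significant_only = TRUE,
                         ...) {
  df <- dplyr::filter(results, .data$estimand == !!estimand,
                      !is.na(.data$estimate))
  if (significant_only) df <- dplyr::filter(df, .data$significant)
  if (!nrow(df)) {
    abort("nothing to plot (no rows match)", class = "mediscreen_input_error")
  }
  df <- dplyr::mutate(df, trait = stats::reorder(.data$trait, .data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$trait,
                                   colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = paste(estimand, "estimate (95% CI)"), y = NULL,
                  colour = "stratum") +
    ggplot2::theme_minimal()
}

#' @rdname plot_effects
#' @param object A `trait_results` tibble.
#' @method autoplot trait_results
#' @export
autoplot.trait_results <- function(object, estimand = "NDE",
                                   significant_only = TRUE, ...) {
  plot_effects(object, estimand = estimand,
               significant_only = significant_only, ...)
}

#' Direct vs indirect share of the total effect per trait
#'
#' Stacked horizontal bars of `nde_fraction` and `nie_fraction` (which sum to
#' one where defined) for every trait with a defined decomposition.
#'
#' @param results A `trait_results` tibble containing NDE rows with defined
#'   fractions.
#' @return A ggplot object.
#' @export
plot_effect_fractions <- function(results) {
  df <- results |>
    dplyr::filter(.data$estimand == "NDE", !is.na(.data$nde_fraction)) |>
    dplyr::select("trait", "stratum", "mediator", "nde_fraction",
                  "nie_fraction") |>
    tidyr::pivot_longer(c("nde_fraction", "nie_fraction"),
                        names_to = "component", values_to = "fraction") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            nde_fraction = "NDE",
                                            nie_fraction = "NIE"))
  if (!nrow(df)) {
    abort("no defined effect fractions to plot",
          class = "mediscreen_input_error")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$trait,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$stratum ~ .data$mediator) +
    ggplot2::labs(x = "fraction of total effect", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
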
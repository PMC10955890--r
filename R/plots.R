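#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_pointrange
#'   geom_col geom_hline geom_vline geom_density geom_abline labs coord_flip
#'   facet_wrap theme_minimal .data
NULL

#' Plot per-subject update-bias posteriors
#'
#' Posterior means with central 95% intervals for both bias indices, one
#' point range per subject, ordered by the self-efficacy bias.
#'
#' @param object An `update_bias_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.update_bias_fit <- function(object, ...) {
  td <- tidy(object)
  ord <- td |>
    dplyr::filter(.data$term == "self_efficacy_bias") |>
    dplyr::arrange(.data$estimate) |>
    dplyr::pull(.data$subject_id)
  td$subject_id <- factor(td$subject_id, levels = ord)
  ggplot(td, aes(x = .data$subject_id, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high),
      size = 0.2) +
    facet_wrap(~term) +
    coord_flip() +
    labs(
      x = "subject", y = "update bias (posterior mean, 95% interval)",
      title = "Positive update bias by subject"
    ) +
    theme_minimal()
}

#' Plot the posterior of the group-level median bias
#'
#' @param object An `hdi_result` from [group_bias_hdi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdi_result <- function(object, ...) {
  draws <- attr(object, "draws")
  ggplot(data.frame(x = draws), aes(x = .data$x)) +
    geom_density(fill = "grey80") +
    geom_vline(xintercept = 0, linetype = 2) +
    geom_vline(
      xintercept = c(object$hdi_low, object$hdi_high),
      colour = "steelblue"
    ) +
    labs(
      x = sprintf("group median %s update bias", object$which),
      y = "posterior density",
      title = sprintf(
        "Group-level bias: %s (median %.3f, %d%% HDI [%.3f, %.3f])",
        object$decision, object$point, round(100 * object$level),
        object$hdi_low, object$hdi_high
      )
    ) +
    theme_minimal()
}

#' Plot varimax component loadings
#'
#' Bar chart of the rotated loadings of each questionnaire scale on each
#' retained component.
#'
#' @param object A `component_profile` from [pca_varimax()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_profile <- function(object, ...) {
  td <- tidy(object)
  td$scale <- factor(td$scale, levels = rev(rownames(object$loadings)))
  ggplot(td, aes(x = .data$scale, y = .data$loading)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    facet_wrap(~component) +
    coord_flip() +
    labs(
      x = NULL, y = "rotated loading",
      title = "Questionnaire loadings on retained components"
    ) +
    theme_minimal()
}

#' Scatterplot for the bias vs. empirical-correlation posterior check
#'
#' @param ppc A [ppc_bias_vs_empirical()] result.
#' @return A ggplot object.
#' @export
plot_ppc_scatter <- function(ppc) {
  dat <- attr(ppc, "data")
  if (is.null(dat)) abort("No scatter data attached; rerun ppc_bias_vs_empirical().")
  ggplot(dat, aes(x = .data$model_bias, y = .data$empirical_bias)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    labs(
      x = "model update bias (posterior mean)",
      y = "empirical correlation difference (pos - neu)",
      title = sprintf("Posterior check: r = %.2f (n = %d)", ppc$r, ppc$n)
    ) +
    theme_minimal()
}
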
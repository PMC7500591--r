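#' Volcano plot of a two-stage differential analysis
#'
#' Log2 fold change against -log10 p for the stage-1-selected
#' annotations, with the significance calls at the fit's alpha
#' highlighted.
#'
#' @param object an `ennb_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.ennb_fit <- function(object, ...) {
  d <- dplyr::filter(object$results, selected, !is.na(p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = log2_fc,
                                  y = -log10(p_value),
                                  colour = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#c0392b")) +
    ggplot2::labs(
      x = bquote(log[2] ~ "fold change (" * .(object$treatment_levels[2]) *
                   " vs " * .(object$treatment_levels[1]) * ")"),
      y = bquote(-log[10] ~ "p"),
      colour = paste0("p < ", format(object$alpha)),
      title = sprintf("Site %s, %s normalization", object$site,
                      object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Operating-characteristic plot of a calibration grid
#'
#' Mean empirical FDR and mean power per grid point, against alpha by
#' normalization method. The FDR curve is what the threshold choice is
#' based on.
#'
#' @param object a `calibration_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.calibration_grid <- function(object, ...) {
  means <- glance(object)
  d <- tidyr::pivot_longer(means, c(mean_fdr, mean_power),
                           names_to = "metric", values_to = "value")
  d$metric <- ifelse(d$metric == "mean_fdr", "empirical FDR", "power")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(alpha), y = value,
                                  colour = method, group = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "significance threshold alpha", y = NULL,
                  colour = "normalization") +
    ggplot2::theme_minimal()
}

#' Group-means plot of a plant-trait fit
#'
#' Treatment-group means with +/- 1 SE bars computed from the underlying
#' observations.
#'
#' @param object a `trait_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.trait_fit <- function(object, ...) {
  d <- object$model$model
  means <- dplyr::summarise(
    dplyr::group_by(d, treatment),
    mean = mean(value), se = sd(value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = treatment, y = mean,
                                      fill = treatment)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se,
                                        ymax = mean + se),
                           width = 0.15) +
    ggplot2::labs(
      x = NULL,
      y = paste0(paste(object$trait_name, collapse = "/"),
                 " (", paste(object$units, collapse = "/"), ")"),
      title = sprintf("Effect %.3g (p = %.3g)", object$estimate,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Venn-region bar chart for a cross-site term comparison
#'
#' @param object a `term_comparison` from [compare_sites()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.term_comparison <- function(object, ...) {
  d <- object$regions
  d$region <- factor(d$region, levels = d$region[order(d$n_sites,
                                                       d$region)])
  ggplot2::ggplot(d, ggplot2::aes(x = region, y = n_terms,
                                  fill = factor(n_sites))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "site combination (exclusive region)",
                  y = "GO terms", fill = "sites sharing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
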
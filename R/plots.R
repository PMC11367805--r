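#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_vline geom_abline facet_wrap labs theme_minimal
NULL

#' Forest plot of a meta-analysis
#'
#' @param object An `mpt_meta`.
#' @param ... Unused.
#' @return A ggplot: per-study estimates with CIs and the pooled row.
#' @export
#' @method autoplot mpt_meta
autoplot.mpt_meta <- function(object, ...) {
  d <- forest_data(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot(d, aes(x = .data$r, y = .data$label)) +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, na.rm = TRUE) +
    geom_point(aes(shape = .data$pooled, size = .data$pooled),
               show.legend = FALSE, na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18)) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4)) +
    labs(x = "correlation (r scale)", y = NULL) +
    theme_minimal()
}

#' Group-level posterior summary plot of a fitted MPT model
#'
#' @param object An `mpt_fit`.
#' @param ... Unused.
#' @return A ggplot of probability-scale group means with 95% credible
#'   intervals.
#' @export
#' @method autoplot mpt_fit
autoplot.mpt_fit <- function(object, ...) {
  g <- object$group
  ggplot(g, aes(x = .data$mean_prob,
                y = factor(.data$parameter,
                           levels = rev(object$model$parameters)))) +
    geom_errorbarh(aes(xmin = .data$ci_low_prob, xmax = .data$ci_high_prob),
                   height = 0.2) +
    geom_point(size = 2) +
    ggplot2::xlim(0, 1) +
    labs(x = "group mean (probability scale)", y = NULL,
         title = paste("Hierarchical", object$model$name, "fit")) +
    theme_minimal()
}

#' Scatterplot of occasion-1 vs occasion-2 individual estimates
#'
#' One panel per parameter, with the identity line marking perfect
#' consistency.
#'
#' @param estimates Tidy individual estimates with columns `participant`,
#'   `occasion`, `parameter`, `estimate` (see [parameter_consistency()]).
#' @return A ggplot.
#' @export
plot_consistency <- function(estimates) {
  wide <- estimates |>
    dplyr::select("participant", "occasion", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "occasion", values_from = "estimate",
                       names_prefix = "occ")
  ggplot(wide, aes(x = .data$occ1, y = .data$occ2)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    geom_point(alpha = 0.5, size = 1) +
    facet_wrap(~parameter) +
    labs(x = "occasion 1 estimate", y = "occasion 2 estimate") +
    theme_minimal()
}
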
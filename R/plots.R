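#' Plot incidence curves split at the median delta-feature
#'
#' @param object an `incidence_curve` from [incidence_by_median_split()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.incidence_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$timepoint, y = .data$incidence,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                                      fill = .data$group), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "moderate-to-severe xerostomia incidence",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a dose vs delta-feature regression
#'
#' @param object a `delta_linfit` from [fit_linear()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.delta_linfit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("slope %.3g, R² %.2f, p %.3g",
                                     object$slope, object$r_squared,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Bootstrap selection-frequency bar chart
#'
#' @param study a `delta_study` (or a selection-frequency tibble with
#'   `week`, `group`, `feature`, `count`)
#' @param group feature group to display
#' @param top_n features shown per week, by frequency
#' @return a ggplot
#' @export
plot_selection_frequency <- function(study, group = "geometric", top_n = 8) {
  freq <- if (inherits(study, "delta_study")) study$selection_frequency else study
  freq <- dplyr::filter(freq, .data$group == !!group)
  freq <- dplyr::slice_max(dplyr::group_by(freq, .data$week), .data$count,
                           n = top_n, with_ties = FALSE)
  ggplot2::ggplot(freq, ggplot2::aes(x = stats::reorder(.data$feature,
                                                        .data$count),
                                     y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~week, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "bootstrap selection count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
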
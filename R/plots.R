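#' Plot a bias experiment
#'
#' Per parameter: mean estimate with an empirical-standard-error bar for each
#' method, and the generating true value as a horizontal mark — the standard
#' display for comparing estimator bias across methods.
#'
#' @param object A `bias_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_sim
#' @export
autoplot.bias_sim <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$mean_estimate,
                                  colour = .data$method, shape = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_estimate - .data$empirical_se,
                   ymax = .data$mean_estimate + .data$empirical_se),
      position = ggplot2::position_dodge(width = 0.5), width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true_value), colour = "grey40",
                        shape = 95, size = 8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "estimated effect on survival",
                  title = "Estimator bias: joint SEM vs stepwise baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot cross-validation performance
#'
#' RMSE and out-of-fold R-squared per method.
#'
#' @param object A `cond_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cond_cv
#' @export
autoplot.cond_cv <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("rmse", "r_squared"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value,
                                  fill = .data$method)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$repeats, object$folds)) +
    ggplot2::theme_minimal()
}

#' Scree plot of a principal component analysis
#'
#' @param object A `cond_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cond_pca
#' @export
autoplot.cond_pca <- function(object, ...) {
  d <- glance(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = 100 * .data$variance_explained)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "variance explained (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
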
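#' Violin plot of the three adequacy metrics across species
#'
#' @param adequacy Output of [compute_adequacy()].
#' @return A ggplot object.
#' @export
plot_adequacy <- function(adequacy) {
  adequacy |>
    tidyr::pivot_longer(cols = c("mic", "trc", "csb"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(metric = toupper(.data$metric)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.08, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Per-species data adequacy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Median and percentile ribbon plot of a temporal series
#'
#' Median line with a 5th-95th percentile ribbon per metric, as produced by
#' [summarize_series()].
#'
#' @param summaries Output of [summarize_series()].
#' @return A ggplot object.
#' @export
plot_series <- function(summaries) {
  summaries |>
    dplyr::mutate(metric = toupper(.data$metric)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p05, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "year", y = "metric value",
                  title = "Adequacy over time (median, 5th-95th percentile)") +
    ggplot2::theme_minimal()
}

#' Coefficient (forest) plot for trait models
#'
#' Point estimates and 95% confidence intervals for every term (intercept
#' omitted), one colour per adequacy metric.
#'
#' @param object A `trait_model_set` from [run_all_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_model_set
#' @export
autoplot.trait_model_set <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(metric = toupper(.data$metric)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$estimate, y = .data$term,
                                 colour = .data$metric)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL, colour = "metric") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trait_model_set
#' @method autoplot trait_model_fit
#' @export
autoplot.trait_model_fit <- function(object, ...) {
  autoplot.trait_model_set(
    structure(list(fits = list(object)), class = "trait_model_set"))
}
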
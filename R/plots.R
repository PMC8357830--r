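#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stepwise gaze errors over fixation events
#'
#' Shows the regression, prediction and fixed-model error curves per
#' fixation event, as percentages of the screen width.
#'
#' @param object A [stepwise_errors()] result.
#' @param log_scale Use a log10 error axis (useful when the fixed model
#'   diverges).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaze_stepwise
#' @export
autoplot.gaze_stepwise <- function(object, log_scale = FALSE, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("event", "error_regression",
                                  "error_prediction", "error_fixed")],
    -"event", names_to = "estimate", values_to = "error",
    names_prefix = "error_"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$error,
                                        colour = .data$estimate)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "fixation event", y = "error (% screen width)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a model-comparison table
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object: mean regression and prediction error per model.
#' @method autoplot gaze_model_comparison
#' @export
autoplot.gaze_model_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("model", "n_terms", "mean_regression",
                                  "mean_prediction")],
    dplyr::starts_with("mean_"), names_to = "metric", values_to = "error",
    names_prefix = "mean_"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$model, .data$n_terms),
                                   y = .data$error, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean error (% screen width)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Cumulative error-distribution plot
#'
#' Empirical cumulative distributions of the progressive-prediction and
#' fixed-model errors, the standard way of reading off "for 95% of
#' estimations the error was below X% of screen width".
#'
#' @param errors A `gaze_stepwise` tibble (or pooled rows from several).
#' @param q Reference percentile drawn as a guide (default 95).
#' @return A ggplot object.
#' @export
plot_error_cdf <- function(errors, q = 95) {
  ok <- errors$prediction_defined
  df <- dplyr::bind_rows(
    tibble::tibble(error = sort(errors$error_prediction[ok]),
                   model = "progressive"),
    tibble::tibble(error = sort(errors$error_fixed[ok]), model = "fixed")
  )
  df <- dplyr::filter(df, !is.na(.data$error))
  df <- df |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(cdf = dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error, y = .data$cdf,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = q / 100, linetype = "dashed") +
    ggplot2::labs(x = "prediction error (% screen width)",
                  y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gaze session's target layout and pose schedule
#'
#' @param object A `gaze_session`.
#' @param ... Unused.
#' @return A ggplot object of the target layout in screen coordinates.
#' @method autoplot gaze_session
#' @export
autoplot.gaze_session <- function(object, ...) {
  tg <- object$script$targets
  sc <- object$script$screen
  ggplot2::ggplot(tg, ggplot2::aes(x = .data$gx, y = .data$gy)) +
    ggplot2::geom_point(colour = "darkgreen", size = 2) +
    ggplot2::geom_path(alpha = 0.3) +
    ggplot2::scale_y_reverse(limits = c(sc$height, 0)) +
    ggplot2::xlim(0, 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "gx (screen widths)", y = "gy") +
    ggplot2::theme_minimal()
}
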
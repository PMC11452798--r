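#' Plot adoption curves
#'
#' Per-round cumulative adopter proportions, one line per session, facetted by
#' setting.
#'
#' @param curve A tibble from [observed_curve()] (columns `session_id`,
#'   `setting`, `round`, `proportion`).
#' @return A ggplot object.
#' @export
plot_adoption_curves <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$round, y = .data$proportion,
    group = .data$session_id, colour = factor(.data$session_id)
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$setting)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Round", y = "Proportion of adopters",
                  colour = "Session") +
    ggplot2::theme_minimal()
}

#' Plot a fitted adopter curve against the observation
#'
#' @param object An `innovation_fit` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot innovation_fit
#' @export
autoplot.innovation_fit <- function(object, ...) {
  df <- augment(object)
  long <- tidyr::pivot_longer(df, c("observed", "predicted"),
                              names_to = "series", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(.data$round, .data$proportion,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = long[long$series == "observed", ]) +
    ggplot2::labs(
      x = "Round", y = "Proportion of adopters",
      title = sprintf("c = %s, delta = %.2f, T = %g (MSE = %.2g)",
                      ifelse(is.na(object$c), "-", format(object$c)),
                      object$delta, object$T, object$mse),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the decay-law comparison
#'
#' @param curves A tibble from [decay_law_experiment()].
#' @return A ggplot object.
#' @export
plot_decay_comparison <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$round, .data$proportion,
                                       colour = .data$law)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Round", y = "Mean proportion of adopters",
                  colour = "Decay law") +
    ggplot2::theme_minimal()
}

#' Plot per-setting permutation feature importance
#'
#' @param importance A tibble from [permutation_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance, ggplot2::aes(.data$feature, .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$setting)) +
    ggplot2::labs(x = NULL, y = "OOB permutation importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
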
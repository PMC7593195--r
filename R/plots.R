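#' Plot selection gradients per generation
#'
#' @param object A [selection_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qgsel_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data$beta,
                                       colour = .data$line)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "generation", y = "selection gradient",
                  title = "Realized selection gradients")
}

#' Plot posterior genetic trends
#'
#' @param object A [genetic_trends()] result.
#' @param envelope Optional [simulate_drift_null()] result overlaid as a
#'   drift-null band.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qgsel_trend <- function(object, envelope = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$generation,
                                            colour = .data$line,
                                            fill = .data$line))
  if (!is.null(envelope)) {
    p <- p + ggplot2::geom_ribbon(
      data = envelope$envelope,
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.1, colour = NA)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "generation", y = "mean breeding value",
                  title = "Posterior genetic trends (median and 95% interval)")
}

#' Plot a drift-null envelope
#'
#' @param object A [simulate_drift_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qgsel_drift <- function(object, ...) {
  ggplot2::ggplot(object$envelope,
                  ggplot2::aes(x = .data$generation, colour = .data$line)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "generation", y = "line-mean breeding value",
                  title = "Genetic space reachable by drift (95% envelope)")
}

#' Plot predicted selection-response trajectories
#'
#' @param object A [predict_response()] result.
#' @param scale `"data"` or `"latent"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qgsel_prediction <- function(object, scale = "data", ...) {
  sub <- object[object$scale == scale, ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "generation", y = paste0(scale, "-scale mean"),
                  title = "Predicted selection response (median and 95% interval)")
}
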
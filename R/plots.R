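#' Plot a training schedule
#'
#' Tile plot of trial order: each of the 360 training trials coloured by
#' discrimination, with epoch boundaries for progressive schedules. Makes
#' the structural difference between interleaved and progressive training
#' visible at a glance.
#'
#' @param schedule A schedule tibble.
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule) {
  ggplot2::ggplot(schedule,
                  ggplot2::aes(x = .data$trial, y = .data$pair,
                               fill = .data$pair)) +
    ggplot2::geom_tile(height = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "trial", y = NULL,
                  title = paste(schedule$condition[1], "training schedule")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed vs model-expected inference performance
#'
#' @param object A `ti_fit` object.
#' @param ... Unused.
#' @return A ggplot object comparing observed correct counts with the
#'   fitted model's expected counts per inferred discrimination.
#' @export
autoplot.ti_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$prob, c("k", "expected_k"),
                            names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_discrete(labels = c(expected_k = "expected", k = "observed")) +
    ggplot2::labs(
      y = sprintf("correct of %d", object$n), x = NULL, fill = NULL,
      title = sprintf("%s model fit (kappa = %.2f, H = %.3f)",
                      object$model, object$kappa, object$H)
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a behavioural GLMM
#'
#' @param object A `ti_glmm` object.
#' @param ... Unused.
#' @return A ggplot object of estimates with approximate 95% intervals.
#' @export
autoplot.ti_glmm <- function(object, ...) {
  ggplot2::ggplot(object$coef,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = paste("behavioural model:", object$design$outcome)) +
    ggplot2::theme_minimal()
}

#' Distance effect in an RSA table or fit
#'
#' Scatter of Fisher-z similarity against transitive distance with the
#' fitted fixed-effect trend; negative slopes are the signature of a
#' structural (map-like) representation.
#'
#' @param object A `ti_rsa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ti_rsa <- function(object, ...) {
  b0 <- object$coef$estimate[object$coef$term == "(Intercept)"]
  b1 <- object$coef$estimate[object$coef$term == "distance_c"]
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$distance, y = .data$z)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.3) +
    ggplot2::geom_abline(intercept = b0 - b1 * mean(object$table$distance),
                         slope = b1, colour = "red") +
    ggplot2::labs(x = "transitive distance", y = "Fisher z similarity",
                  title = sprintf("%s-hierarchy distance effect (b = %.4f)",
                                  object$scope, b1)) +
    ggplot2::theme_minimal()
}
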
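#' Plot a decoding time-course
#'
#' @param object A `decoding_timecourse`.
#' @param ... Unused.
#' @return A ggplot object: accuracy over time with the chance level dashed.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = attr(object, "chance"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = "Decoding accuracy",
      title = sprintf("%s decoding, %g Hz", attr(object, "scheme"),
                      attr(object, "rate_hz"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decoding_timecourse
#' @export
glance.decoding_timecourse <- function(x, ...) {
  post <- x$time_ms > 0
  tibble(scheme = attr(x, "scheme"), rate_hz = attr(x, "rate_hz"),
         chance = attr(x, "chance"), lambda = attr(x, "lambda"),
         peak_accuracy = max(x$accuracy[post]),
         peak_ms = x$time_ms[post][which.max(x$accuracy[post])])
}

#' @param x A `decoding_timecourse`.
#' @rdname autoplot.decoding_timecourse
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble(time_ms = x$time_ms, accuracy = x$accuracy,
         scheme = attr(x, "scheme"), rate_hz = attr(x, "rate_hz"),
         chance = attr(x, "chance"))
}

#' Plot a temporal-generalization matrix
#'
#' @param object A `tg_matrix`.
#' @param ... Unused.
#' @return A ggplot raster of accuracy over train x test time.
#' @export
autoplot.tg_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test_time_ms, y = .data$train_time_ms,
                               fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = sprintf("Test time (ms, %g Hz)", object$test_rate_hz),
      y = sprintf("Train time (ms, %g Hz)", object$train_rate_hz),
      fill = "Accuracy",
      title = sprintf("Temporal generalization (%s)", object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a Bayes-factor time-course
#'
#' @param object A `bayes_result`.
#' @param ... Unused.
#' @return A ggplot of log10 BF10 with the evidence thresholds marked.
#' @export
autoplot.bayes_result <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 10
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms,
                                       y = log10(.data$bf10),
                                       colour = .data$evidence)) +
    ggplot2::geom_hline(yintercept = c(-log10(thr), log10(thr)),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(
      supports_alt = "#d55e00", inconclusive = "grey55",
      supports_null = "grey80")) +
    ggplot2::labs(x = "Time (ms)", y = expression(log[10] ~ BF[10])) +
    ggplot2::theme_minimal()
}

#' Plot a partial-correlation RSA time-course
#'
#' @param object A `partial_corr_timecourse`.
#' @param ... Unused.
#' @return A ggplot of the partial correlation over time.
#' @export
autoplot.partial_corr_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$r_partial)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = "Partial correlation",
      title = sprintf("%s model (controls: %s)", attr(object, "model"),
                      paste(attr(object, "controls"), collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a channel-searchlight map
#'
#' @param object A `searchlight_map`.
#' @param ... Unused.
#' @return A ggplot raster of accuracy over channel x time.
#' @export
autoplot.searchlight_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$channel,
                                       fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time (ms)", y = "Channel (searchlight centre)",
                  fill = "Accuracy") +
    ggplot2::theme_minimal()
}
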
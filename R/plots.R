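#' Plot a decoding time course
#'
#' Accuracy against time with the chance level as a dashed reference.
#'
#' @param object A `decoding_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "accuracy (%)",
                  title = sprintf("%s decoding", object$factor)) +
    ggplot2::theme_minimal()
}

#' Plot a temporal generalization matrix
#'
#' @param object A `tempgen_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tempgen_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_time, y = .data$train_time,
                                   fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "accuracy (%)") +
    ggplot2::labs(x = "testing time (ms)", y = "training time (ms)",
                  title = sprintf("temporal generalization (%s)",
                                  object$factor)) +
    ggplot2::theme_minimal()
}

#' Plot fusion commonality time courses
#'
#' Total shared variance as a grey ribbon with task and category
#' commonalities overlaid, facetted by ROI.
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_result <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, c("c_task", "c_category"),
                              names_to = "model", values_to = "commonality")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(
      data = df,
      ggplot2::aes(ymin = 0, ymax = .data$r2_total), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$commonality,
                                    colour = .data$model)) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::scale_colour_manual(
      values = c(c_task = "#2166ac", c_category = "#b2182b"),
      labels = c(c_task = "task", c_category = "category")) +
    ggplot2::labs(x = "time (ms)", y = expression(R^2),
                  colour = "unique to") +
    ggplot2::theme_minimal()
}

#' Plot a 1D cluster test result
#'
#' Observed t-curve, per-time cluster-inducing threshold, and significant
#' clusters marked along the time axis.
#'
#' @param object A `cluster_result` with `dims == 1`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  if (object$dims != 1L) {
    abort("autoplot is only defined for 1D cluster results")
  }
  df <- tibble(time = object$time, t = object$t_obs,
               threshold = object$thresh)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time (ms)", y = "t value") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    p <- p + ggplot2::annotate(
      "segment", x = sig$start_time, xend = sig$end_time,
      y = max(df$t) * 1.05, yend = max(df$t) * 1.05,
      linewidth = 2, colour = "#2166ac")
  }
  p
}
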
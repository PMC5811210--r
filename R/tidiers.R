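#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoding time course
#'
#' @param x A `decoding_timecourse`.
#' @param ... Unused.
#' @return Tibble with `subject`, `time`, `accuracy`, `chance`, `factor`.
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble(subject = x$subject %||% NA_character_, time = x$time,
         accuracy = x$accuracy, chance = x$chance, factor = x$factor)
}

#' @rdname tidy.decoding_timecourse
#' @export
glance.decoding_timecourse <- function(x, ...) {
  tibble(factor = x$factor, subject = x$subject %||% NA_character_,
         n_time = length(x$time), mean_accuracy = mean(x$accuracy),
         peak_accuracy = max(x$accuracy),
         peak_time = x$time[which.max(x$accuracy)], chance = x$chance)
}

#' Tidy a temporal generalization matrix
#'
#' @param x A `tempgen_matrix`.
#' @param ... Unused.
#' @return Long tibble with `train_time`, `test_time`, `accuracy`.
#' @export
tidy.tempgen_matrix <- function(x, ...) {
  tidyr::expand_grid(train_time = x$train_time, test_time = x$test_time) |>
    dplyr::mutate(accuracy = as.vector(t(x$accuracy)),
                  subject = x$subject %||% NA_character_)
}

#' @rdname tidy.tempgen_matrix
#' @export
glance.tempgen_matrix <- function(x, ...) {
  diag_acc <- diag(x$accuracy)
  tibble(factor = x$factor, n_train = length(x$train_time),
         n_test = length(x$test_time), mean_accuracy = mean(x$accuracy),
         mean_diagonal = mean(diag_acc), chance = x$chance)
}

#' Tidy a fusion result
#'
#' @param x A `fusion_result` (already a long tibble; returned as plain
#'   tibble).
#' @param ... Unused.
#' @export
tidy.fusion_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x) != ""])
}

#' @rdname tidy.fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$roi),
    peak_r2 = max(.data$r2_total),
    peak_c_task = max(.data$c_task),
    peak_c_category = max(.data$c_category),
    peak_c_task_time = .data$time_ms[which.max(.data$c_task)],
    peak_c_category_time = .data$time_ms[which.max(.data$c_category)],
    .groups = "drop")
}

#' Tidy a cluster test result
#'
#' @param x A `cluster_result` or `fusion_cluster_result`.
#' @param ... Unused.
#' @return The cluster table.
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(dims = x$dims, n_perm = x$n_perm, alpha = x$alpha,
         crit_size = x$crit_size, n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$significant))
}

#' @rdname tidy.cluster_result
#' @export
tidy.fusion_cluster_result <- function(x, ...) x$clusters

#' Tidy a bootstrap latency CI
#'
#' @param x A `peak_ci`.
#' @param ... Unused.
#' @return One-row tibble with estimate and CI bounds (ms).
#' @export
tidy.peak_ci <- function(x, ...) {
  tibble(mode = x$mode, estimate = x$estimate, conf_low = x$lower,
         conf_high = x$upper, n_boot = x$n_boot,
         flat_window = x$flat_window, n_failed = x$n_failed)
}
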
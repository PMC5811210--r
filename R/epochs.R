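#' Epoched multichannel time series
#'
#' Container for epoched data: a trials x channels x time array plus its time
#' axis (ms relative to task-cue onset), sampling rate, the trial table, and a
#' provenance list that records every transformation applied. After spatial
#' PCA the channel axis holds component scores and `channel_type` becomes
#' `"component"`.
#'
#' @param data Numeric array, trials x channels x time, all values finite.
#' @param time Numeric vector of time stamps in ms, strictly increasing with
#'   uniform spacing `1000 / sampling_rate`.
#' @param sampling_rate Sampling rate in Hz.
#' @param trials Tibble with one row per trial (see [generate_design()]).
#' @param subject Subject identifier.
#' @param channel_type `"sensor"` or `"component"`.
#' @param provenance List of processing metadata.
#' @return An object of class `epochs`.
#' @export
new_epochs <- function(data, time, sampling_rate, trials,
                       subject = "s01", channel_type = "sensor",
                       provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a trials x channels x time array")
  }
  if (!all(is.finite(data))) abort("`data` must be finite")
  if (dim(data)[1] != nrow(trials)) {
    abort("number of trials in `data` and `trials` differ")
  }
  if (dim(data)[3] != length(time)) {
    abort("time axis length does not match `data`")
  }
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - 1000 / sampling_rate)) > 1e-6)) {
    abort("`time` must increase uniformly at 1000 / sampling_rate ms steps")
  }
  structure(
    list(data = data, time = as.double(time),
         sampling_rate = as.double(sampling_rate),
         trials = as_tibble(trials), subject = subject,
         channel_type = channel_type, provenance = provenance),
    class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs> subject %s: %d trials x %d %ss x %d samples (%g Hz, %g..%g ms)\n",
    x$subject, d[1], d[2], x$channel_type, d[3], x$sampling_rate,
    min(x$time), max(x$time)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epochs <- function(x) dim(x$data)

# subset trials, keeping everything else aligned
epochs_subset_trials <- function(x, idx) {
  x$data <- x$data[idx, , , drop = FALSE]
  x$trials <- x$trials[idx, ]
  x
}

# non-catch trials only (analyses exclude catch trials by default)
epochs_experimental <- function(x) {
  if (!"is_catch" %in% names(x$trials)) return(x)
  epochs_subset_trials(x, which(!x$trials$is_catch))
}

# view the array as time x (trial*channel) without changing trial/channel order
epochs_time_matrix <- function(x) {
  d <- dim(x$data)
  m <- aperm(x$data, c(3L, 1L, 2L))
  dim(m) <- c(d[3], d[1] * d[2])
  m
}

epochs_from_time_matrix <- function(x, m, time = x$time,
                                    sampling_rate = x$sampling_rate) {
  d <- dim(x$data)
  dim(m) <- c(length(time), d[1], d[2])
  x$data <- aperm(m, c(2L, 3L, 1L))
  x$time <- time
  x$sampling_rate <- sampling_rate
  x
}
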
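#' Preprocessing configuration
#'
#' Parameters for the sensor-to-component preprocessing chain, applied in the
#' fixed order filter -> spatial PCA -> low-variance component removal ->
#' baseline normalization -> temporal smoothing -> downsampling.
#'
#' @param band Band-pass edges in Hz. The defaults (0.1-300 Hz) suit
#'   1200 Hz recordings; both edges must lie below the Nyquist frequency of
#'   the data being filtered.
#' @param notch Line frequency in Hz; the notch is applied at this frequency
#'   and all harmonics below Nyquist. `NULL` disables it.
#' @param variance_drop_fraction Fraction of total variance defining the
#'   low-variance component suffix to remove (default 1%).
#' @param max_drop_fraction Cap on the fraction of components that may be
#'   removed (default 50%).
#' @param baseline_window Baseline window in ms: `c(-100, 0)` (pre-cue) for
#'   task analyses, `c(1900, 2000)` (pre-stimulus) for object analyses.
#' @param hdhm_ms Gaussian smoothing kernel half duration at half maximum in
#'   ms; the kernel's FWHM is `2 * hdhm_ms`.
#' @param target_rate Output sampling rate in Hz; the input rate must be an
#'   integer multiple.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.1, 300), notch = 60,
                              variance_drop_fraction = 0.01,
                              max_drop_fraction = 0.5,
                              baseline_window = c(-100, 0),
                              hdhm_ms = 15, target_rate = 120) {
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  }
  check_scalar(variance_drop_fraction, "variance_drop_fraction")
  if (variance_drop_fraction <= 0 || variance_drop_fraction >= 1) {
    abort("`variance_drop_fraction` must lie in (0, 1)")
  }
  check_scalar(max_drop_fraction, "max_drop_fraction")
  if (max_drop_fraction <= 0 || max_drop_fraction > 1) {
    abort("`max_drop_fraction` must lie in (0, 1]")
  }
  stopifnot(length(baseline_window) == 2L,
            baseline_window[2] > baseline_window[1])
  structure(
    list(band = band, notch = notch,
         variance_drop_fraction = variance_drop_fraction,
         max_drop_fraction = max_drop_fraction,
         baseline_window = baseline_window, hdhm_ms = hdhm_ms,
         target_rate = target_rate),
    class = "preprocess_config")
}

# squared magnitude response of an IIR filter on the given digital
# frequency grid (radians/sample)
digital_gain2 <- function(flt, omega) {
  ew <- exp(-1i * outer(omega, seq_along(flt$b) - 1))
  num <- drop(ew %*% flt$b)
  ew <- exp(-1i * outer(omega, seq_along(flt$a) - 1))
  den <- drop(ew %*% flt$a)
  Mod(num / den)^2
}

#' Zero-phase band-pass and line-noise filtering
#'
#' Applies, per trial and channel, a zero-phase band-pass (2nd-order
#' Butterworth high-pass at `band[1]`, 4th-order Butterworth low-pass at
#' `band[2]`) plus 2nd-order Butterworth band-stop filters (+-2 Hz) at the
#' line frequency and each harmonic below Nyquist. The cascade's squared
#' magnitude response is applied in the frequency domain to the
#' mirror-extended epoch, which is exactly zero-phase and free of the edge
#' transients a forward-backward IIR pass leaves on epochs shorter than the
#' filter's settling time (a 0.1 Hz high-pass settles over ~10 s). Shape is
#' preserved.
#'
#' @param epochs An [new_epochs()] object.
#' @param config A [preprocess_config()].
#' @return Filtered `epochs`.
#' @export
filter_epochs <- function(epochs, config = preprocess_config()) {
  stopifnot(inherits(epochs, "epochs"))
  fs <- epochs$sampling_rate
  nyq <- fs / 2
  band <- config$band
  if (any(band >= nyq)) {
    abort(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                  max(band), nyq))
  }

  filters <- list(
    signal::butter(2, band[1] / nyq, type = "high"),
    signal::butter(4, band[2] / nyq, type = "low"))
  if (!is.null(config$notch)) {
    harmonics <- config$notch * seq_len(floor(0.95 * nyq / config$notch))
    for (f0 in harmonics) {
      filters <- c(filters, list(
        signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")))
    }
  }

  n_ext <- 2L * length(epochs$time)
  omega <- 2 * pi * (seq_len(n_ext) - 1L) / n_ext
  gain <- rep(1, n_ext)
  for (flt in filters) gain <- gain * digital_gain2(flt, omega)

  m <- epochs_time_matrix(epochs)
  m <- fft_filter_matrix(m, gain)
  out <- epochs_from_time_matrix(epochs, m)
  out$provenance$filter <- list(band = band, notch = config$notch)
  out
}

# zero-phase spectral filtering of each column: mirror-extend (even
# extension, continuous at both joins), multiply the spectrum by the real
# gain, invert, truncate; chunked over columns to bound memory
fft_filter_matrix <- function(m, gain, chunk = 1024L) {
  T <- nrow(m)
  out <- matrix(0, T, ncol(m))
  for (start in seq(1L, ncol(m), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(m))
    ext <- rbind(m[, cols, drop = FALSE],
                 m[T:1, cols, drop = FALSE])
    spec <- stats::mvfft(ext) * gain
    out[, cols] <- Re(stats::mvfft(spec, inverse = TRUE)[seq_len(T), ,
                                                         drop = FALSE]) /
      (2 * T)
  }
  out
}

#' Fit a purely spatial PCA and project to component scores
#'
#' Channels are decorrelated by an eigendecomposition of the channel
#' covariance computed from all trials' samples concatenated in time. The
#' rotation is purely spatial: each output sample depends only on the same
#' input sample, so the MEG signal is never mixed in time. Component score
#' covariance is diagonal and total variance about the fit mean is conserved.
#'
#' @param epochs An [new_epochs()] object with >= 2 channels.
#' @return A list with `model` (class `pca_model`: loadings, center,
#'   per-component variances sorted descending, fit metadata) and `scores`
#'   (an `epochs` object on the component axis).
#' @export
fit_spatial_pca <- function(epochs) {
  stopifnot(inherits(epochs, "epochs"))
  d <- dim(epochs$data)
  if (d[2] < 2L) abort("spatial PCA needs at least 2 channels")
  if (d[1] * d[3] < 2L) abort("spatial PCA needs at least 2 samples")
  if (!all(is.finite(epochs$data))) abort("non-finite data")

  x <- aperm(epochs$data, c(1L, 3L, 2L))   # trial, time, channel
  dim(x) <- c(d[1] * d[3], d[2])
  center <- colMeans(x)
  # covariance with algebraic centering (no centered copy of x)
  cv <- (crossprod(x) - nrow(x) * tcrossprod(center)) / (nrow(x) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  loadings <- eig$vectors
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) loadings[, j] <- -loadings[, j]
  }
  variances <- pmax(eig$values, 0)

  scores <- x %*% loadings
  rm(x)
  scores <- scores - rep(drop(center %*% loadings), each = nrow(scores))
  dim(scores) <- c(d[1], d[3], d[2])
  scores <- aperm(scores, c(1L, 3L, 2L))

  model <- structure(
    list(loadings = loadings, center = center, variances = variances,
         n_trials = d[1], n_samples = d[1] * d[3]),
    class = "pca_model")
  out <- epochs
  out$data <- scores
  out$channel_type <- "component"
  out$provenance$pca <- list(variances = variances, n_components = d[2])
  list(model = model, scores = out)
}

#' How many components survive the low-variance removal rule
#'
#' Removes the largest suffix of ascending-variance components whose summed
#' variance does not exceed `variance_drop_fraction` of the total. If that
#' suffix would exceed `max_drop_fraction` of the components, exactly
#' `floor(max_drop_fraction * n)` are removed instead. With 272 components
#' whose bottom-1%-variance suffix spans more than half of them, the cap
#' branch retains 136.
#'
#' @param variances Per-component variances.
#' @param variance_drop_fraction,max_drop_fraction See [preprocess_config()].
#' @return Integer count of retained components.
#' @export
retained_after_variance_drop <- function(variances,
                                         variance_drop_fraction = 0.01,
                                         max_drop_fraction = 0.5) {
  n <- length(variances)
  asc <- sort(variances)
  n_drop <- sum(cumsum(asc) <= variance_drop_fraction * sum(variances))
  cap <- floor(max_drop_fraction * n)
  if (n_drop > cap) n_drop <- cap
  as.integer(n - n_drop)
}

#' Remove low-variance components
#'
#' Applies the removal rule of [retained_after_variance_drop()] to a
#' component dataset, dropping the lowest-variance components.
#'
#' @param scores Component `epochs` from [fit_spatial_pca()].
#' @param model The matching `pca_model`.
#' @param variance_drop_fraction,max_drop_fraction See [preprocess_config()].
#' @return The reduced component `epochs`, with the retained count recorded
#'   in provenance.
#' @export
drop_low_variance_components <- function(scores, model,
                                         variance_drop_fraction = 0.01,
                                         max_drop_fraction = 0.5) {
  stopifnot(inherits(scores, "epochs"), inherits(model, "pca_model"))
  n_keep <- retained_after_variance_drop(model$variances,
                                         variance_drop_fraction,
                                         max_drop_fraction)
  keep <- order(model$variances, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)
  scores$data <- scores$data[, keep, , drop = FALSE]
  scores$provenance$component_drop <- list(
    n_total = length(model$variances), n_retained = n_keep,
    variance_drop_fraction = variance_drop_fraction,
    max_drop_fraction = max_drop_fraction)
  scores
}

#' Univariate noise normalization against a baseline window
#'
#' For each component, the mean and standard deviation over all trials'
#' baseline samples (pooled across trials) are computed; the mean is
#' subtracted from, and the SD divided into, every sample of that component.
#' After normalization the pooled baseline window has mean 0 and SD 1 per
#' component, and re-applying the operation is the identity on those
#' statistics.
#'
#' @param scores Component (or sensor) `epochs`.
#' @param window_ms Baseline window `c(from, to)` in ms (inclusive), at least
#'   2 samples.
#' @return Normalized `epochs` with the window recorded in provenance.
#' @export
baseline_normalize <- function(scores, window_ms = c(-100, 0)) {
  apply_baseline(scores, baseline_stats(scores, window_ms))
}

# pooled per-component baseline mean and SD
baseline_stats <- function(scores, window_ms) {
  stopifnot(inherits(scores, "epochs"))
  idx <- which(scores$time >= window_ms[1] & scores$time <= window_ms[2])
  if (length(idx) < 2L) abort("baseline window must contain >= 2 samples")
  base <- scores$data[, , idx, drop = FALSE]
  d <- dim(base)
  base <- aperm(base, c(1L, 3L, 2L))
  dim(base) <- c(d[1] * d[3], d[2])
  mu <- colMeans(base)
  sdv <- apply(base, 2L, sd)
  if (any(sdv == 0)) {
    abort(sprintf("baseline SD is zero for component(s): %s",
                  paste(which(sdv == 0), collapse = ", ")))
  }
  list(window_ms = window_ms, mean = mu, sd = sdv)
}

# per-component affine normalization; commutes with the (unit-sum, purely
# temporal) smoothing kernel, which the pipeline exploits to smooth once and
# derive both baseline branches
apply_baseline <- function(scores, stats) {
  nd <- dim(scores$data)
  scores$data <- (scores$data - rep(stats$mean, each = nd[1])) /
    rep(stats$sd, each = nd[1])
  scores$provenance$baseline <- list(window_ms = stats$window_ms,
                                     mean = stats$mean, sd = stats$sd)
  scores
}

# unit-sum Gaussian taps; sigma follows FWHM = 2 * hdhm
gaussian_kernel <- function(hdhm_ms, sampling_rate) {
  sigma_ms <- hdhm_ms / sqrt(2 * log(2))
  dt <- 1000 / sampling_rate
  hw <- ceiling(4 * sigma_ms / dt)
  k <- dnorm(seq(-hw, hw) * dt, sd = sigma_ms)
  k / sum(k)
}

#' Gaussian temporal smoothing followed by decimation
#'
#' Convolves each component time course with a unit-sum Gaussian kernel whose
#' full width at half maximum is `2 * hdhm_ms` (so `sigma = hdhm_ms /
#' sqrt(2 log 2)`, about 12.74 ms for the default 15 ms), truncated at
#' +-4 sigma with reflection at the epoch edges, then keeps every
#' (rate ratio)-th sample starting at the epoch start. The rate ratio must be
#' an integer.
#'
#' @param scores Component `epochs`.
#' @param hdhm_ms Kernel half duration at half maximum in ms (> 0).
#' @param target_rate Output rate in Hz (<= current rate).
#' @return Smoothed, downsampled `epochs`.
#' @export
smooth_and_downsample <- function(scores, hdhm_ms = 15, target_rate = 120) {
  stopifnot(inherits(scores, "epochs"))
  if (hdhm_ms <= 0) abort("`hdhm_ms` must be positive")
  fs <- scores$sampling_rate
  if (target_rate > fs) abort("`target_rate` exceeds the current rate")
  ratio <- fs / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf("rate ratio %g Hz / %g Hz is not an integer", fs,
                  target_rate))
  }
  ratio <- round(ratio)

  kern <- gaussian_kernel(hdhm_ms, fs)
  keep <- seq(1L, length(scores$time), by = ratio)
  m <- epochs_time_matrix(scores)
  m <- cpp_smooth_decimate(m, kern, keep - 1L)
  out <- epochs_from_time_matrix(scores, m, time = scores$time[keep],
                                 sampling_rate = target_rate)
  out$provenance$smoothing <- list(hdhm_ms = hdhm_ms,
                                   sigma_ms = hdhm_ms / sqrt(2 * log(2)),
                                   target_rate = target_rate)
  out
}

#' Run the full preprocessing chain
#'
#' filter -> spatial PCA -> low-variance component removal -> baseline
#' normalization -> smoothing -> downsampling, each stage a pure function of
#' its inputs and the configuration.
#'
#' @param epochs Sensor `epochs`.
#' @param config A [preprocess_config()].
#' @return A component `epochs` object with full provenance.
#' @export
preprocess_epochs <- function(epochs, config = preprocess_config()) {
  x <- filter_epochs(epochs, config)
  fit <- fit_spatial_pca(x)
  x <- drop_low_variance_components(fit$scores, fit$model,
                                    config$variance_drop_fraction,
                                    config$max_drop_fraction)
  x <- baseline_normalize(x, config$baseline_window)
  smooth_and_downsample(x, config$hdhm_ms, config$target_rate)
}
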
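# single-trial epochs holding a deterministic waveform on every channel
wave_epochs <- function(fn, sampling_rate = 600, n_channels = 2) {
  n <- round(5.1 * sampling_rate)
  time <- -100 + (seq_len(n) - 1) * 1000 / sampling_rate
  x <- fn(time / 1000)   # seconds
  data <- aperm(array(x, dim = c(n, 1, n_channels)), c(2, 3, 1))
  trials <- tibble::tibble(trial = 1, task = "color", category = "catA",
                           is_catch = FALSE)
  new_epochs(data, time, sampling_rate, trials)
}

test_that("the notch removes a 60 Hz tone to below 1% residual", {
  ep <- wave_epochs(function(t) sin(2 * pi * 60 * t))
  out <- filter_epochs(ep, preprocess_config(band = c(0.1, 200)))
  mid <- seq(500, dim(ep$data)[3] - 500)   # away from epoch edges
  expect_lt(max(abs(out$data[1, 1, mid])), 0.01)
})

test_that("a DC offset is removed by the 0.1 Hz high-pass", {
  ep <- wave_epochs(function(t) rep(5, length(t)))
  out <- filter_epochs(ep, preprocess_config(band = c(0.1, 200)))
  expect_lt(max(abs(out$data)), 0.05)
})

test_that("an in-band 10 Hz tone passes within 5% amplitude", {
  ep <- wave_epochs(function(t) sin(2 * pi * 10 * t))
  out <- filter_epochs(ep, preprocess_config(band = c(0.1, 200)))
  mid <- seq(500, dim(ep$data)[3] - 500)
  amp <- max(abs(out$data[1, 1, mid]))
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
})

test_that("band edges at or above Nyquist are rejected", {
  ep <- wave_epochs(function(t) sin(t), sampling_rate = 100)
  expect_error(filter_epochs(ep, preprocess_config(band = c(0.1, 60))),
               "Nyquist")
})

test_that("spatial PCA decorrelates channels and conserves variance", {
  d <- generate_design(small_spec(), seed = 1)
  ep <- generate_subject_epochs(d, ground_truth(), n_channels = 6,
                                sampling_rate = 40, seed = 2)
  fit <- fit_spatial_pca(ep)
  x <- aperm(fit$scores$data, c(1, 3, 2))
  dim(x) <- c(prod(dim(ep$data)[c(1, 3)]), 6)
  cv <- cov(x)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_equal(sum(diag(cv)), sum(fit$model$variances), tolerance = 1e-8)
  y <- aperm(ep$data, c(1, 3, 2))
  dim(y) <- dim(x)
  expect_equal(sum(diag(cov(y))), sum(fit$model$variances),
               tolerance = 1e-8)
  expect_true(all(diff(fit$model$variances) <= 1e-12))
})

test_that("duplicated channels produce near-zero trailing variances", {
  d <- generate_design(small_spec(), seed = 1)
  ep <- generate_subject_epochs(d, ground_truth(), n_channels = 4,
                                sampling_rate = 40, seed = 3)
  ep$data <- ep$data[, c(1, 2, 1, 2), ]   # rank 2
  fit <- fit_spatial_pca(ep)
  expect_lt(fit$model$variances[3] / fit$model$variances[1], 1e-10)
})

test_that("spatial PCA never mixes time", {
  trials <- tibble::tibble(trial = 1:2, task = "color", category = "catA",
                           is_catch = FALSE)
  n <- 204
  time <- -100 + (seq_len(n) - 1) * 1000 / 40
  set.seed(4)
  data <- array(0, dim = c(2, 3, n))
  data[, , 50] <- matrix(rnorm(6), 2, 3)   # impulse at one sample
  ep <- new_epochs(data, time, 40, trials)
  fit <- fit_spatial_pca(ep)
  # away from the impulse, scores are constant over time (only the projected
  # channel mean remains): the rotation touched no other samples
  rng <- apply(fit$scores$data[, , -50], c(1, 2), function(v) diff(range(v)))
  expect_lt(max(rng), 1e-10)
})

test_that("low-variance removal follows the cumulative suffix rule", {
  v <- c(50, 30, 10, 5, 3, 1, 0.5, 0.3, 0.15, 0.05)
  expect_equal(retained_after_variance_drop(v), 6L)
  expect_equal(retained_after_variance_drop(rep(10, 10)), 10L)
  # 272 components whose low-variance suffix exceeds the 50% cap -> 136
  v272 <- c(rep(100, 10), rep(1e-3, 262))
  expect_equal(retained_after_variance_drop(v272), 136L)
})

test_that("drop_low_variance_components removes the lowest-variance scores", {
  d <- generate_design(small_spec(), seed = 1)
  ep <- generate_subject_epochs(d, ground_truth(), n_channels = 5,
                                sampling_rate = 40, seed = 5)
  ep$data[, 5, ] <- ep$data[, 5, ] * 1e-4   # one tiny-variance channel
  fit <- fit_spatial_pca(ep)
  red <- drop_low_variance_components(fit$scores, fit$model)
  expect_equal(dim(red$data)[2], 4L)
  expect_equal(red$provenance$component_drop$n_retained, 4L)
})

test_that("baseline normalization matches its definition and is idempotent", {
  trials <- tibble::tibble(trial = 1:3, task = "color", category = "catA",
                           is_catch = FALSE)
  n <- 204
  time <- -100 + (seq_len(n) - 1) * 1000 / 40
  set.seed(6)
  data <- array(rnorm(3 * 2 * n, mean = 5, sd = 2), dim = c(3, 2, n))
  ep <- new_epochs(data, time, 40, trials)
  out <- baseline_normalize(ep, c(-100, 0))
  win <- which(time >= -100 & time <= 0)
  base <- out$data[, , win]
  for (j in 1:2) {
    expect_equal(mean(base[, j, ]), 0, tolerance = 1e-12)
    expect_equal(sd(as.vector(base[, j, ])), 1, tolerance = 1e-12)
  }
  # hand arithmetic: sample x with baseline mean mu and SD s -> (x - mu)/s
  const <- ep
  const$data[] <- 9
  vals <- rep(c(3, 7), length.out = 3 * length(win))
  for (j in 1:2) const$data[, j, win] <- vals
  mu <- mean(vals)
  sdv <- sd(vals)
  normed <- baseline_normalize(const, c(-100, 0))
  expect_equal(normed$data[1, 1, max(win) + 1], (9 - mu) / sdv)
  # renormalizing the output leaves baseline statistics unchanged
  again <- baseline_normalize(out, c(-100, 0))
  expect_equal(again$data, out$data, tolerance = 1e-12)
})

test_that("a constant component is a zero-SD error naming the component", {
  trials <- tibble::tibble(trial = 1:2, task = "color", category = "catA",
                           is_catch = FALSE)
  n <- 204
  time <- -100 + (seq_len(n) - 1) * 1000 / 40
  data <- array(rnorm(2 * 2 * n), dim = c(2, 2, n))
  data[, 2, ] <- 3
  ep <- new_epochs(data, time, 40, trials)
  expect_error(baseline_normalize(ep, c(-100, 0)), "component\\(s\\): 2")
})

test_that("smoothing preserves constants and matches the Gaussian form", {
  ep <- wave_epochs(function(t) rep(2, length(t)), sampling_rate = 1200,
                    n_channels = 2)
  out <- smooth_and_downsample(ep, hdhm_ms = 15, target_rate = 120)
  expect_equal(dim(out$data)[3], 612L)      # 6120 samples -> 612
  expect_equal(max(abs(out$data - 2)), 0, tolerance = 1e-12)

  # unit impulse: response equals the normalized truncated Gaussian,
  # sigma = 30 / (2 sqrt(2 ln 2)) ~ 12.7394 ms
  imp <- wave_epochs(function(t) as.double(seq_along(t) == 3001),
                     sampling_rate = 1200, n_channels = 2)
  sm <- smooth_and_downsample(imp, hdhm_ms = 15, target_rate = 1200)
  sigma <- 15 / sqrt(2 * log(2))
  expect_equal(sigma, 12.7394, tolerance = 1e-4)
  dt <- 1000 / 1200
  hw <- ceiling(4 * sigma / dt)
  kern <- dnorm(seq(-hw, hw) * dt, sd = sigma)
  kern <- kern / sum(kern)
  got <- sm$data[1, 1, 3001 + seq(-hw, hw)]
  expect_equal(as.double(got), kern, tolerance = 1e-12)
})

test_that("smoothing validates its arguments", {
  ep <- wave_epochs(function(t) sin(t), sampling_rate = 300)
  expect_error(smooth_and_downsample(ep, hdhm_ms = 0, target_rate = 100),
               "positive")
  expect_error(smooth_and_downsample(ep, hdhm_ms = 15, target_rate = 120),
               "not an integer")
  expect_error(smooth_and_downsample(ep, hdhm_ms = 15, target_rate = 600),
               "exceeds")
})

test_that("the full chain runs in order and records provenance", {
  d <- generate_design(small_spec(), seed = 1)
  ep <- generate_subject_epochs(d, ground_truth(), n_channels = 6,
                                sampling_rate = 100, seed = 7)
  out <- preprocess_epochs(ep, preprocess_config(band = c(0.1, 40),
                                                 target_rate = 50))
  expect_equal(out$sampling_rate, 50)
  expect_equal(out$channel_type, "component")
  expect_true(all(c("filter", "pca", "component_drop", "baseline",
                    "smoothing") %in% names(out$provenance)))
})
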
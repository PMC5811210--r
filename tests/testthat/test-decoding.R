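test_that("supertrials partition trials without replacement", {
  tr <- make_trials(n_per_cell = 5)              # 20 trials per category
  ep <- make_test_epochs(tr, n_channels = 4, sampling_rate = 20, seed = 1)
  st <- make_supertrials(ep, "category", group_size = 10, rng_seed = 2)
  expect_equal(dim(st$data)[1], 4L)              # 2 classes x 2 groups
  used <- sort(unlist(st$mapping))
  expect_equal(used, unique(used))               # each trial at most once
  expect_equal(length(used), 40L)                # all 40 trials used
  # supertrial = mean of its members
  g1 <- st$mapping[[1]]
  expect_equal(st$data[1, , ],
               apply(ep$data[g1, , ], c(2, 3), mean), tolerance = 1e-12)
})

test_that("leftover trials are dropped and identical trials average to themselves", {
  tr <- make_trials(n_per_cell = 5)
  tr43 <- tr[c(seq_len(nrow(tr)), 1:6), ]        # 43 trials of catA per task mix
  tr43$trial <- seq_len(nrow(tr43))
  ep <- make_test_epochs(tr43, n_channels = 3, sampling_rate = 20, seed = 2)
  counts <- table(tr43$category)
  st <- make_supertrials(ep, "category", group_size = 10, rng_seed = 1)
  expect_equal(as.integer(table(st$class)),
               as.integer(floor(counts / 10)))
  # identical trials: supertrial equals the trial pattern
  ep2 <- ep
  for (i in seq_len(dim(ep2$data)[1])) ep2$data[i, , ] <- ep2$data[1, , ]
  st2 <- make_supertrials(ep2, "category", group_size = 10, rng_seed = 1)
  expect_equal(st2$data[1, , ], ep2$data[1, , ], tolerance = 1e-12)
})

test_that("too few trials per class is an error", {
  tr <- make_trials(n_per_cell = 1)
  ep <- make_test_epochs(tr, n_channels = 3, sampling_rate = 20, seed = 3)
  expect_error(make_supertrials(ep, "category", group_size = 10),
               "fewer trials")
})

test_that("ordering accuracy scores direction and ties", {
  expect_equal(ordering_accuracy(c(0.7, -0.2), c("A", "B")), 100)
  expect_equal(ordering_accuracy(c(-0.2, 0.7), c("A", "B")), 0)
  expect_equal(ordering_accuracy(c(0.3, 0.3), c("A", "B")), 50)
  # positive-class convention: first class lexicographically
  expect_equal(ordering_accuracy(c(0.1, 0.9), c("B", "A")), 100)
})

test_that("ordering accuracy equals brute-force two-sample AUC", {
  set.seed(42)
  ok <- vapply(1:1000, function(i) {
    dv <- rnorm(2)
    auc <- 100 * (0.5 * (dv[1] == dv[2]) + (dv[1] > dv[2]))
    identical(ordering_accuracy(dv, c("A", "B")), auc)
  }, TRUE)
  expect_true(all(ok))
})

test_that("noiseless separable class patterns decode at 100%", {
  tr <- make_trials(n_per_cell = 4)
  sig <- function(trial, time, nch) {
    outer(class_pattern(trial$category, nch), rep(1, length(time)))
  }
  ep <- make_test_epochs(tr, n_channels = 6, sampling_rate = 20,
                         noise_sd = 0.01, seed = 4, signal_fn = sig)
  tc <- decode_timecourse(ep, decoding_config(supertrial_size = 2,
                                              n_iterations = 3,
                                              label_factor = "category",
                                              seed = 5))
  expect_true(all(tc$accuracy == 100))
})

test_that("structureless data decode at chance", {
  tr <- make_trials(n_per_cell = 6, categories = c("catA", "catB"))
  ep <- make_test_epochs(tr, n_channels = 6, sampling_rate = 30, seed = 6)
  tc <- decode_timecourse(ep, decoding_config(supertrial_size = 3,
                                              n_iterations = 20,
                                              label_factor = "category",
                                              seed = 7))
  expect_lt(abs(mean(tc$accuracy) - 50), 3)
})

test_that("decoding at time t ignores every other time point", {
  tr <- make_trials(n_per_cell = 4)
  ep <- make_test_epochs(tr, n_channels = 4, sampling_rate = 20, seed = 8)
  cfg <- decoding_config(supertrial_size = 2, n_iterations = 2,
                         label_factor = "category", seed = 9)
  tc1 <- decode_timecourse(ep, cfg)
  k <- 37
  ep2 <- ep
  scramble <- dim(ep2$data)[3]:1
  ep2$data <- ep2$data[, , scramble]
  ep2$data[, , k] <- ep$data[, , k]
  ep2$time <- ep$time
  tc2 <- decode_timecourse(ep2, cfg)
  expect_equal(tc2$accuracy[k], tc1$accuracy[k])
})

test_that("the compiled solver agrees with libsvm on its decision ordering", {
  skip_if_not_installed("e1071")
  set.seed(10)
  agree <- 0
  n_prob <- 100
  for (i in seq_len(n_prob)) {
    d <- 5
    X <- matrix(rnorm(16 * d), 16)
    y <- rep(c(1, -1), each = 8)
    X[y == 1, ] <- X[y == 1, ] + rnorm(d)
    xt <- matrix(rnorm(2 * d), 2)
    w <- repdyn:::cpp_svm_weights(t(cbind(X, 1)), y, 1)
    dv_mine <- cbind(xt, 1) %*% w
    fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
    dv_svm <- attr(predict(fit, xt, decision.values = TRUE),
                   "decision.values")
    sign_svm <- sign(dv_svm[1] - dv_svm[2]) *
      (if (colnames(dv_svm) == "1/-1") 1 else -1)
    agree <- agree + (sign(dv_mine[1] - dv_mine[2]) == sign_svm)
  }
  expect_gte(agree / n_prob, 0.95)
})

test_that("temporal generalization matches the time course on the diagonal", {
  tr <- make_trials(n_per_cell = 4)
  sig <- function(trial, time, nch) {
    p <- class_pattern(trial$category, nch)
    outer(p, as.double(time > 1000)) * 0.8
  }
  ep <- make_test_epochs(tr, n_channels = 5, sampling_rate = 10,
                         seed = 11, signal_fn = sig)
  cfg <- decoding_config(supertrial_size = 2, n_iterations = 4,
                         label_factor = "category", seed = 12)
  tg <- temporal_generalization(ep, cfg)
  tc <- decode_timecourse(ep, cfg)
  expect_equal(diag(tg$accuracy), tc$accuracy, tolerance = 1e-12)
})

test_that("disjoint-epoch orthogonal patterns give a block generalization matrix", {
  tr <- make_trials(n_per_cell = 4)
  # pattern 1 in the first half, an orthogonal pattern in the second half
  sig <- function(trial, time, nch) {
    base <- class_pattern(trial$category, nch)
    p1 <- c(base[1:3], rep(0, nch - 3))
    p2 <- c(rep(0, nch - 3), base[1:3])
    outer(p1, as.double(time < 2000)) + outer(p2, as.double(time >= 2000))
  }
  ep <- make_test_epochs(tr, n_channels = 6, sampling_rate = 10,
                         noise_sd = 0.3, seed = 13, signal_fn = sig)
  cfg <- decoding_config(supertrial_size = 2, n_iterations = 6,
                         label_factor = "category", seed = 14)
  tg <- temporal_generalization(ep, cfg)
  first <- ep$time < 2000
  within1 <- mean(tg$accuracy[first, first])
  within2 <- mean(tg$accuracy[!first, !first])
  across <- mean(tg$accuracy[first, !first])
  expect_gt(within1, 90)
  expect_gt(within2, 90)
  expect_lt(abs(across - 50), 12)
})

test_that("a constant pattern generalizes across the whole epoch", {
  tr <- make_trials(n_per_cell = 4)
  sig <- function(trial, time, nch) {
    outer(class_pattern(trial$category, nch), rep(1, length(time)))
  }
  ep <- make_test_epochs(tr, n_channels = 5, sampling_rate = 10,
                         noise_sd = 0.2, seed = 15, signal_fn = sig)
  tg <- temporal_generalization(ep, decoding_config(supertrial_size = 2,
                                                    n_iterations = 3,
                                                    label_factor = "category",
                                                    seed = 16))
  expect_gt(min(tg$accuracy), 90)
})

test_that("within/between task-type decoding separates pattern change from gain", {
  # orthogonal object patterns per task type: between at chance
  tr <- make_trials(n_per_cell = 6)
  sig_orth <- function(trial, time, nch) {
    base <- class_pattern(trial$category, nch)
    p <- if (trial$task_type == "perceptual") {
      c(base[1:3], rep(0, nch - 3))
    } else {
      c(rep(0, nch - 3), base[1:3])
    }
    outer(p, rep(1, length(time)))
  }
  ep <- make_test_epochs(tr, n_channels = 6, sampling_rate = 10,
                         noise_sd = 0.4, seed = 17, signal_fn = sig_orth)
  cfg <- decoding_config(supertrial_size = 3, n_iterations = 6,
                         label_factor = "category", seed = 18)
  res <- cross_tasktype_object_decode(ep, cfg)
  expect_gt(mean(res$within$accuracy), 85)
  expect_lt(abs(mean(res$between$accuracy) - 50), 10)

  # same patterns, different gain: both high, strength not quality differs
  sig_gain <- function(trial, time, nch) {
    g <- if (trial$task_type == "conceptual") 2 else 1
    outer(g * class_pattern(trial$category, nch), rep(1, length(time)))
  }
  ep2 <- make_test_epochs(tr, n_channels = 6, sampling_rate = 10,
                          noise_sd = 0.4, seed = 19, signal_fn = sig_gain)
  res2 <- cross_tasktype_object_decode(ep2, cfg)
  expect_gt(mean(res2$within$accuracy), 85)
  expect_gt(mean(res2$between$accuracy), 85)
})

test_that("decoding refuses a baseline normalized for the other factor", {
  tr <- make_trials(n_per_cell = 4)
  ep <- make_test_epochs(tr, n_channels = 4, sampling_rate = 20, seed = 20)
  ep$provenance$baseline <- list(window_ms = c(-100, 0))
  cfg <- decoding_config(supertrial_size = 2, n_iterations = 1,
                         label_factor = "category", seed = 1)
  expect_error(decode_timecourse(ep, cfg), "expects")
  ep$provenance$baseline <- list(window_ms = c(1900, 2000))
  expect_silent(decode_timecourse(ep, cfg))
})

test_that("doubling iterations shrinks the Monte-Carlo noise of the curve", {
  tr <- make_trials(n_per_cell = 6, categories = c("catA", "catB"))
  ep <- make_test_epochs(tr, n_channels = 5, sampling_rate = 10, seed = 21)
  sd_for <- function(n_iter) {
    reps <- vapply(1:8, function(r) {
      tc <- decode_timecourse(ep, decoding_config(
        supertrial_size = 3, n_iterations = n_iter,
        label_factor = "category", seed = 100 + 13 * r + n_iter))
      mean(tc$accuracy[1:10])
    }, 1.0)
    sd(reps)
  }
  s1 <- sd_for(2)
  s2 <- sd_for(8)
  expect_lt(s2, s1)     # 4x iterations must reduce the replicate spread
})
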
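test_that("condition means are identities on single-trial and duplicated cells", {
  tr <- make_trials(n_per_cell = 1, categories = paste0("c", 1:2))
  ep <- make_test_epochs(tr, n_channels = 4, sampling_rate = 10, seed = 1)
  cm <- condition_mean_patterns(ep)
  expect_equal(dim(cm$patterns)[1], 8L)   # 4 tasks x 2 categories
  i <- which(condition_labels(cm$condition_order) ==
               paste(ep$trials$task[1], ep$trials$category[1], sep = "."))
  expect_equal(cm$patterns[i, , ], ep$data[1, , ], tolerance = 1e-12)

  # duplicating every trial leaves the means unchanged
  ep2 <- ep
  ep2$data <- ep$data[rep(seq_len(nrow(tr)), 2), , ]
  ep2$trials <- ep$trials[rep(seq_len(nrow(tr)), 2), ]
  cm2 <- condition_mean_patterns(ep2)
  expect_equal(cm2$patterns, cm$patterns, tolerance = 1e-12)
})

test_that("the canonical design yields 32 condition patterns", {
  ep_trials <- generate_design(design_spec(), seed = 1)
  set.seed(2)
  data <- array(rnorm(nrow(ep_trials) * 3 * 5), dim = c(nrow(ep_trials), 3, 5))
  time <- seq(0, by = 100, length.out = 5)
  ep <- new_epochs(data, time, 10, ep_trials)
  cm <- condition_mean_patterns(ep)
  expect_equal(dim(cm$patterns), c(32L, 3L, 5L))
  expect_equal(condition_labels(cm$condition_order)[1:8],
               paste("color", category_levels(8), sep = "."))
})

test_that("a missing condition cell is an error naming the cell", {
  tr <- make_trials(n_per_cell = 1, categories = paste0("c", 1:2))
  tr <- tr[!(tr$task == "tilt" & tr$category == "c2"), ]
  ep <- make_test_epochs(tr, n_channels = 3, sampling_rate = 10, seed = 3)
  expect_error(condition_mean_patterns(ep), "tilt.c2")
})

test_that("the correlation-distance RDM hits its anchor values", {
  base <- rnorm(20)
  p <- rbind(a = base, b = 2 * base + 5,          # r = 1 -> 0
             c = -base,                            # r = -1 vs a -> 2
             d = rnorm(20))
  r <- compute_rdm(p)
  expect_equal(r$matrix["a", "b"], 0, tolerance = 1e-12)
  expect_equal(r$matrix["a", "c"], 2, tolerance = 1e-12)
  expect_true(all(diag(r$matrix) == 0))
  expect_equal(r$matrix, t(r$matrix))

  # exactly orthogonal (zero-correlation) patterns -> dissimilarity 1
  q <- rbind(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1))
  expect_equal(compute_rdm(q)$matrix["x", "y"], 1, tolerance = 1e-12)

  expect_error(compute_rdm(rbind(rep(1, 5), rnorm(5))), "variance")
})

test_that("compute_rdm is invariant to affine rescaling of patterns", {
  set.seed(4)
  p <- matrix(rnorm(5 * 30), 5)
  r1 <- compute_rdm(p)
  r2 <- compute_rdm(p * 3.7 - 11)
  expect_equal(r1$matrix, r2$matrix, tolerance = 1e-10)
})

test_that("model RDMs have the combinatorial zero/one counts", {
  tm <- model_rdm("task")
  cm <- model_rdm("category")
  expect_equal(sum(rdv(tm) == 0), 112)   # 4 * choose(8, 2)
  expect_equal(sum(rdv(tm) == 1), 384)
  expect_equal(sum(rdv(cm) == 0), 48)    # 8 * choose(4, 2)
  expect_equal(sum(rdv(cm) == 1), 448)
  expect_error(model_rdm("exemplar"), "arg")
  # the two models never share a zero off the diagonal
  both <- rdv(tm) == 0 & rdv(cm) == 0
  expect_false(any(both))
})

test_that("rdv vectorizes the lower triangle and round-trips", {
  tm <- model_rdm("task")
  v <- rdv(tm)
  expect_length(v, 496)
  ones <- matrix(1, 4, 4) - diag(4)
  expect_equal(as.double(rdv(ones)), rep(1, 6))
  expect_equal(as.double(rdv(tm)), as.double(rdv(t(tm$matrix))))
  back <- rdv_to_rdm(v)
  expect_equal(unname(back$matrix), unname(tm$matrix))
  bad <- matrix(rnorm(16), 4)
  expect_error(rdv(bad), "asymmetric")
})

test_that("group averaging checks ordering and averages entrywise", {
  tm <- model_rdm("task")
  avg <- group_average_rdm(list(tm, tm, tm))
  expect_equal(avg$matrix, tm$matrix)
  flipped <- tm
  flipped$matrix <- 2 - tm$matrix
  diag(flipped$matrix) <- 0
  avg2 <- group_average_rdm(list(tm, flipped))
  expect_true(all(rdv(avg2) == 1))
  permuted <- tm
  permuted$condition_order <- tm$condition_order[c(2:32, 1), ]
  expect_error(group_average_rdm(list(tm, permuted)), "ordering")
})

test_that("rdm time courses track the pattern structure over time", {
  tr <- make_trials(n_per_cell = 2, categories = paste0("c", 1:8))
  sig <- function(trial, time, nch) {
    outer(class_pattern(trial$category, nch), as.double(time >= 2000)) * 3
  }
  ep <- make_test_epochs(tr, n_channels = 8, sampling_rate = 10,
                         noise_sd = 0.3, seed = 5, signal_fn = sig)
  rs <- rdm_timecourse(ep)
  expect_equal(ncol(rs$rdv), choose(32, 2))
  cat_model <- rdv(model_rdm("category", rs$condition_order))
  cors <- apply(rs$rdv, 1, cor, y = cat_model, method = "spearman")
  expect_gt(mean(cors[ep$time >= 2200]), 0.4)
  expect_lt(mean(abs(cors[ep$time < 1800])), 0.15)
})

test_that("RDM CSV files round-trip with their condition ordering", {
  ps <- generate_fmri_patterns(noise_sd = 0.3, n_units = 64, seed = 6)
  r <- roi_rdms(ps)[[1]]
  path <- tempfile(fileext = ".csv")
  write_rdm(r, path)
  back <- read_rdm(path)
  expect_equal(back$matrix, r$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$condition_order$task, r$condition_order$task)
  expect_equal(back$condition_order$category, r$condition_order$category)
})
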
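# coerce per-subject curves to a subjects x time matrix with a time attribute
as_subject_matrix <- function(data, value_col = "accuracy") {
  if (is.matrix(data)) {
    tm <- attr(data, "time") %||% seq_len(ncol(data))
    return(structure(data, time = as.double(tm)))
  }
  if (is.list(data) && length(data) &&
      inherits(data[[1]], "decoding_timecourse")) {
    m <- do.call(rbind, lapply(data, `[[`, "accuracy"))
    return(structure(m, time = data[[1]]$time))
  }
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      data[, c("subject", "time", value_col)],
      names_from = "time", values_from = dplyr::all_of(value_col))
    m <- as.matrix(wide[, -1, drop = FALSE])
    return(structure(m, time = as.double(colnames(wide)[-1])))
  }
  abort("cannot interpret `data` as per-subject time courses")
}

the_sign_cache <- new.env(parent = emptyenv())

# sign matrices; row 1 is always the identity (all +1)
sign_matrix <- function(n, max_exhaustive, n_perm, seed) {
  exhaustive <- n <= 30 && 2^n <= max_exhaustive
  if (exhaustive) {
    key <- sprintf("n%d", n)
    if (!is.null(the_sign_cache[[key]])) return(the_sign_cache[[key]])
    codes <- 0:(2^n - 1)
  } else {
    if (n <= 30 && n_perm > 2^n) {
      abort(sprintf("n_perm = %d exceeds the 2^%d available sign assignments",
                    n_perm, n))
    }
    codes <- with_seed(derive_seed(seed, "signs"), function() {
      if (n <= 30) {
        c(0L, sample.int(2^n - 1L, n_perm - 1L))  # without replacement
      } else {
        NULL
      }
    })
    if (is.null(codes)) {
      m <- with_seed(derive_seed(seed, "signs"), function() {
        matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
               n_perm - 1L, n)
      })
      return(rbind(rep(1, n), m))
    }
  }
  signs <- matrix(1, length(codes), n)
  for (j in seq_len(n)) {
    signs[, j] <- 1 - 2 * bitwAnd(bitwShiftR(codes, j - 1L), 1L)
  }
  if (exhaustive) the_sign_cache[[sprintf("n%d", n)]] <- signs
  signs
}

# smallest cluster size whose exceedance probability under the null is
# <= alpha; "size >= 95th percentile of the max-cluster-size null" read as
# the exact permutation criterion p <= alpha (the two coincide for smooth
# nulls; for discrete extents only the p-value form controls FWER)
crit_from_null <- function(null_max, alpha) {
  cand <- sort(unique(c(null_max, max(null_max) + 1)))
  exceed <- vapply(cand, function(m) mean(null_max >= m), 1.0)
  cand[which(exceed <= alpha)[1]]
}

clusters_from_runs <- function(supra, time, null_max, alpha) {
  r <- rle(as.logical(supra))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  p <- vapply(r$lengths[keep], function(s) mean(null_max >= s), 1.0)
  tibble(
    cluster = seq_len(sum(keep)),
    start_time = time[starts[keep]],
    end_time = time[ends[keep]],
    size = r$lengths[keep],
    p_value = p,
    significant = p <= alpha)
}

new_cluster_result <- function(clusters, t_obs, thresh, time, null_max,
                               alpha, n_perm, seed, dims, extra = list()) {
  structure(
    c(list(clusters = clusters, t_obs = t_obs, thresh = thresh, time = time,
           null_max = null_max, alpha = alpha, n_perm = n_perm, seed = seed,
           dims = dims,
           crit_size = crit_from_null(null_max, alpha)),
      extra),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %dD max-cluster-size test, %d permutations, alpha %g\n",
    x$dims, x$n_perm, x$alpha))
  cat(sprintf("  critical size: %d samples; %d cluster(s), %d significant\n",
              x$crit_size, nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}

#' One-dimensional sign-permutation maximum-cluster-size test
#'
#' Tests, per time point, whether the group mean exceeds `chance`, with
#' cluster-level family-wise error control. Per-subject deviations from
#' chance are sign-flipped over all `2^n` assignments when that count does
#' not exceed `max_exhaustive` (131,072 at n = 17), otherwise over a random
#' sample of `n_perm` assignments drawn without replacement (identity always
#' included). The cluster-inducing threshold is the `1 - alpha` percentile of
#' the permutation t-value distribution at each time point; clusters are
#' maximal runs of supra-threshold observed t-values, and a cluster is
#' significant when its extent is reached or exceeded by at most an `alpha`
#' share of the permutation maximum-cluster-size distribution (the exact
#' permutation reading of "size at the 95th percentile of the null"; for
#' discrete extents only this p-value form controls the family-wise error).
#' One-sided throughout.
#'
#' @param data Per-subject curves: subjects x time matrix (optionally with a
#'   `time` attribute), a list of `decoding_timecourse` objects, or a tidy
#'   data frame with `subject`, `time`, `accuracy` columns.
#' @param chance Chance level to subtract (50 for pairwise decoding).
#' @param alpha Significance level (one-sided).
#' @param max_exhaustive Largest permutation count for which all sign
#'   assignments are enumerated.
#' @param n_perm Number of sampled permutations when not exhaustive.
#' @param seed Integer seed (used only when sampling).
#' @return A `cluster_result` with the cluster table, observed t-curve,
#'   per-time thresholds and the max-cluster-size null.
#' @export
sign_permutation_cluster_1d <- function(data, chance = 50, alpha = 0.05,
                                        max_exhaustive = 2^17,
                                        n_perm = 10000, seed = 1L) {
  X <- as_subject_matrix(data)
  if (nrow(X) < 2L) abort("need at least 2 subjects")
  time <- attr(X, "time")
  signs <- sign_matrix(nrow(X), max_exhaustive, n_perm, seed)
  res <- cpp_cluster_perm_1d(unclass(X) - chance, signs, 1 - alpha)
  clusters <- clusters_from_runs(res$t_obs > res$thresh, time, res$null_max,
                                 alpha)
  new_cluster_result(clusters, as.double(res$t_obs),
                     as.double(res$thresh), time, as.double(res$null_max),
                     alpha, nrow(signs), seed, dims = 1L)
}

#' Two-dimensional sign-permutation cluster test
#'
#' Extension of [sign_permutation_cluster_1d()] to train x test time
#' matrices (temporal generalization). Clusters are 4-connected (edge
#' adjacent) components of supra-threshold points; diagonally touching points
#' belong to different clusters. Permutations are drawn randomly without
#' replacement from the sign-assignment space.
#'
#' @param data List of per-subject matrices (or `tempgen_matrix` objects), or
#'   a subjects x train x test 3D array.
#' @param n_perm Number of permutations (must not exceed `2^n`).
#' @param alpha Significance level (one-sided).
#' @param chance Chance level to subtract.
#' @param seed Integer seed.
#' @return A `cluster_result`; its `clusters` table carries train/test-time
#'   bounding boxes and the full cluster label matrix is in `$labels`.
#' @export
cluster_2d <- function(data, n_perm = 10000, alpha = 0.05, chance = 50,
                       seed = 1L) {
  if (is.list(data) && length(data) && inherits(data[[1]], "tempgen_matrix")) {
    train_time <- data[[1]]$train_time
    test_time <- data[[1]]$test_time
    data <- lapply(data, `[[`, "accuracy")
  } else {
    train_time <- test_time <- NULL
  }
  if (is.array(data) && length(dim(data)) == 3L) {
    data <- lapply(seq_len(dim(data)[1]),
                   function(s) data[s, , , drop = TRUE])
  }
  n <- length(data)
  if (n < 2L) abort("need at least 2 subjects")
  d1 <- nrow(data[[1]])
  d2 <- ncol(data[[1]])
  if (is.null(train_time)) train_time <- seq_len(d1)
  if (is.null(test_time)) test_time <- seq_len(d2)
  X <- do.call(rbind, lapply(data, as.vector)) - chance

  signs <- sign_matrix(n, max_exhaustive = 0, n_perm = n_perm, seed = seed)
  res <- cpp_cluster_perm_2d(X, signs, 1 - alpha, d1, d2)
  t_obs <- matrix(res$t_obs, d1, d2)
  thresh <- matrix(res$thresh, d1, d2)
  labels <- cpp_label_clusters_2d(t_obs > thresh)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  clusters <- dplyr::bind_rows(lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    size <- nrow(w)
    p <- mean(res$null_max >= size)
    tibble(cluster = id,
           train_start = train_time[min(w[, 1])],
           train_end = train_time[max(w[, 1])],
           test_start = test_time[min(w[, 2])],
           test_end = test_time[max(w[, 2])],
           size = size,
           p_value = p,
           significant = p <= alpha)
  }))
  if (length(ids) == 0L) {
    clusters <- tibble(cluster = integer(), train_start = double(),
                       train_end = double(), test_start = double(),
                       test_end = double(), size = integer(),
                       p_value = double(), significant = logical())
  }
  new_cluster_result(clusters, t_obs, thresh, list(train = train_time,
                                                   test = test_time),
                     as.double(res$null_max), alpha, nrow(signs), seed,
                     dims = 2L, extra = list(labels = labels))
}

# RDV index map induced by relabelling conditions with `perm`
rdv_perm_index <- function(perm) {
  n <- length(perm)
  m <- matrix(0L, n, n)
  m[lower.tri(m)] <- seq_len(n * (n - 1L) / 2L)
  m <- m + t(m)
  mp <- m[perm, perm]
  mp[lower.tri(mp)]
}

#' Condition-relabelling randomization test for fusion time courses
#'
#' Builds a null distribution for the commonality (and total R2) time courses
#' by applying random permutations of the rows and columns of the group
#' average MEG RDM (the same relabelling at every time point) and re-running
#' model-based fusion. Per ROI and time point the cluster-inducing threshold
#' is the `1 - alpha` percentile of the null; maximum cluster sizes are
#' pooled across ROIs to correct for multiple comparisons. The identity
#' permutation is always included, so observed curves are one member of the
#' null ensemble and p-values are never zero.
#'
#' @param meg_rdms Group-average `rdm_series`.
#' @param fmri_rdms Named list of per-ROI `rdm` objects.
#' @param models List with `task` and `category` model RDMs.
#' @param n_perm Number of permutations (including the identity).
#' @param alpha Significance level (one-sided).
#' @param seed Integer seed.
#' @param statistics Which fusion statistics to test.
#' @return A `fusion_cluster_result`: cluster table over (statistic, roi),
#'   observed curves, thresholds and pooled null distributions.
#' @export
rdm_randomization_cluster <- function(meg_rdms, fmri_rdms, models =
                                        list(task = model_rdm("task"),
                                             category = model_rdm("category")),
                                      n_perm = 5000, alpha = 0.05, seed = 1L,
                                      statistics = c("c_task", "c_category",
                                                     "r2_total")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  observed <- run_fusion(meg_rdms, fmri_rdms, models)
  rois <- attr(observed, "rois")
  time <- attr(observed, "time")
  n_cond <- nrow(meg_rdms$condition_order)
  n_pair <- ncol(meg_rdms$rdv)
  Tn <- nrow(meg_rdms$rdv)

  a <- rdv(models$task)
  b <- rdv(models$category)
  precomp <- fusion_precompute(lapply(fmri_rdms, rdv), a, b)
  U <- do.call(cbind, precomp)          # n_pair x (4 * n_roi)
  Z <- rank_z_rows(meg_rdms$rdv)        # T x n_pair

  perms <- with_seed(derive_seed(seed, "rdmperm"), function() {
    c(list(seq_len(n_cond)),
      lapply(seq_len(n_perm - 1L), function(i) sample.int(n_cond)))
  })

  null <- lapply(statistics, function(s) {
    lapply(rois, function(r) matrix(NA_real_, n_perm, Tn))
  })
  names(null) <- statistics
  for (s in statistics) names(null[[s]]) <- rois

  for (p in seq_len(n_perm)) {
    idx <- rdv_perm_index(perms[[p]])
    R <- (Z[, idx, drop = FALSE] %*% U) / (n_pair - 1)
    for (ri in seq_along(rois)) {
      cols <- (ri - 1L) * 4L
      y2 <- R[, cols + 1L]^2
      yb2 <- R[, cols + 2L]^2
      ya2 <- R[, cols + 3L]^2
      yab2 <- R[, cols + 4L]^2
      if ("r2_total" %in% statistics) null$r2_total[[ri]][p, ] <- y2
      if ("c_task" %in% statistics) null$c_task[[ri]][p, ] <- yb2 - yab2
      if ("c_category" %in% statistics) {
        null$c_category[[ri]][p, ] <- ya2 - yab2
      }
    }
  }

  q <- 1 - alpha
  results <- list()
  clusters <- list()
  for (s in statistics) {
    thresh <- lapply(null[[s]], function(m) apply(m, 2L, emp_quantile, q = q))
    # pooled across ROIs: per permutation the max cluster size over all ROIs
    null_max <- rep(0, n_perm)
    for (ri in seq_along(rois)) {
      m <- null[[s]][[ri]]
      th <- thresh[[ri]]
      for (p in seq_len(n_perm)) {
        r <- rle(m[p, ] > th)
        mx <- if (any(r$values)) max(r$lengths[r$values]) else 0L
        if (mx > null_max[p]) null_max[p] <- mx
      }
    }
    for (ri in seq_along(rois)) {
      obs <- observed[observed$roi == rois[ri], ][[s]]
      cl <- clusters_from_runs(obs > thresh[[ri]], time, null_max, alpha)
      if (nrow(cl)) {
        cl <- dplyr::mutate(cl, statistic = s, roi = rois[ri], .before = 1L)
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
    results[[s]] <- list(thresh = thresh, null_max = null_max,
                         crit_size = crit_from_null(null_max, alpha))
  }
  clusters <- if (length(clusters)) dplyr::bind_rows(clusters) else {
    tibble(statistic = character(), roi = character(), cluster = integer(),
           start_time = double(), end_time = double(), size = integer(),
           p_value = double(), significant = logical())
  }

  structure(
    list(clusters = clusters, observed = observed, null = results,
         alpha = alpha, n_perm = n_perm, seed = seed, time = time,
         statistics = statistics),
    class = "fusion_cluster_result")
}

#' @export
print.fusion_cluster_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_cluster_result> %d permutations, alpha %g, statistics: %s\n",
    x$n_perm, x$alpha, paste(x$statistics, collapse = ", ")))
  print(x$clusters)
  invisible(x)
}

latency_stat <- function(curve, time, win_idx, mode, onset_criterion) {
  w <- curve[win_idx]
  if (mode == "onset") {
    k <- which(w > onset_criterion)
    if (!length(k)) return(NA_real_)
    return(time[win_idx[k[1]]])
  }
  time[win_idx[which.max(w)]]   # ties: earliest maximum
}

#' Bootstrap confidence interval for a peak (or onset) latency
#'
#' Resamples subjects with replacement `n_boot` times; each draw's statistic
#' is the latency of the maximum of the resampled group-average curve within
#' `window_ms` (`mode = "peak"`), the difference of such latencies between
#' two curve sets (`mode = "peak_difference"`, resampling the same subjects
#' for both), or the earliest time the average curve exceeds
#' `onset_criterion` (`mode = "onset"`). The CI is the 2.5/97.5 percentile of
#' the bootstrap distribution; endpoints lie on the sampled time grid, so at
#' bin width `dt` the interval is conservative by up to `2 * dt`.
#'
#' @param data Per-subject curves (as in [sign_permutation_cluster_1d()]).
#' @param window_ms Search window `c(from, to)` in ms.
#' @param n_boot Number of bootstrap draws.
#' @param mode `"peak"`, `"peak_difference"` or `"onset"`.
#' @param seed Integer seed.
#' @param data2 Second curve set for `mode = "peak_difference"`.
#' @param window2_ms Search window for `data2` (defaults to `window_ms`).
#' @param onset_criterion Threshold for `mode = "onset"`.
#' @return A `peak_ci`: point estimate (full-sample), CI bounds, and
#'   bookkeeping (flat-window flag, failed draws for onset mode).
#' @export
bootstrap_peak_ci <- function(data, window_ms, n_boot = 100000,
                              mode = c("peak", "peak_difference", "onset"),
                              seed = 1L, data2 = NULL,
                              window2_ms = window_ms,
                              onset_criterion = NULL) {
  mode <- match.arg(mode)
  X <- as_subject_matrix(data)
  time <- attr(X, "time")
  n <- nrow(X)
  if (n < 2L) abort("need at least 2 subjects")
  win <- which(time >= window_ms[1] & time <= window_ms[2])
  if (!length(win)) abort("window lies outside the time axis")
  if (mode == "onset" && is.null(onset_criterion)) {
    abort("`onset_criterion` is required for mode = 'onset'")
  }
  if (mode == "peak_difference") {
    if (is.null(data2)) abort("`data2` is required for peak_difference")
    X2 <- as_subject_matrix(data2)
    if (nrow(X2) != n) abort("`data` and `data2` must share subjects")
    win2 <- which(attr(X2, "time") >= window2_ms[1] &
                    attr(X2, "time") <= window2_ms[2])
    time2 <- attr(X2, "time")
  }

  mean_curve <- colMeans(X)
  flat <- length(unique(mean_curve[win])) == 1L
  if (flat) warn("curve is flat in the search window; earliest maximum used")
  estimate <- latency_stat(mean_curve, time, win, mode, onset_criterion)
  if (mode == "peak_difference") {
    estimate <- estimate -
      latency_stat(colMeans(X2), time2, win2, mode, onset_criterion)
  }

  stat <- double(n_boot)
  done <- 0L
  with_seed(derive_seed(seed, "boot"), function() {
    chunk <- 10000L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      W <- t(rmultinom(k, n, rep(1 / n, n))) / n   # resample weights
      M <- W %*% X[, win, drop = FALSE]
      s <- vapply(seq_len(k), function(i) {
        latency_stat(M[i, ], time[win], seq_along(win), mode,
                     onset_criterion)
      }, 1.0)
      if (mode == "peak_difference") {
        M2 <- W %*% X2[, win2, drop = FALSE]
        s <- s - vapply(seq_len(k), function(i) {
          latency_stat(M2[i, ], time2[win2], seq_along(win2), mode,
                       onset_criterion)
        }, 1.0)
      }
      stat[done + seq_len(k)] <<- s
      done <<- done + k
    }
  })

  n_failed <- sum(is.na(stat))
  ci <- quantile(stat, c(0.025, 0.975), na.rm = TRUE, type = 1, names = FALSE)
  structure(
    list(estimate = estimate, lower = ci[1], upper = ci[2], mode = mode,
         n_boot = n_boot, window_ms = window_ms, seed = seed,
         flat_window = flat, n_failed = n_failed, boot = stat),
    class = "peak_ci")
}

#' @export
print.peak_ci <- function(x, ...) {
  cat(sprintf("<peak_ci> %s: %g ms (95%% CI %g to %g), %d bootstrap draws\n",
              x$mode, x$estimate, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Bootstrap peak-latency CI for fusion time courses
#'
#' As [bootstrap_peak_ci()], but each bootstrap draw resamples subjects'
#' MEG RDM series with replacement, averages the RDMs, re-runs model-based
#' fusion against the given ROI, and takes the latency of the chosen fusion
#' statistic within the window.
#'
#' @param subject_rdms List of per-subject `rdm_series`.
#' @param fmri_rdm A single ROI `rdm`.
#' @param models Task and category model RDMs.
#' @param statistic `"c_task"`, `"c_category"` or `"r2_total"`.
#' @param window_ms Search window in ms.
#' @param n_boot Number of bootstrap draws.
#' @param mode `"peak"` or `"onset"`.
#' @param onset_criterion Threshold for onset mode.
#' @param seed Integer seed.
#' @return A `peak_ci`.
#' @export
bootstrap_peak_ci_fusion <- function(subject_rdms, fmri_rdm, models =
                                       list(task = model_rdm("task"),
                                            category = model_rdm("category")),
                                     statistic = c("c_task", "c_category",
                                                   "r2_total"),
                                     window_ms, n_boot = 5000,
                                     mode = c("peak", "onset"),
                                     onset_criterion = NULL, seed = 1L) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  n <- length(subject_rdms)
  if (n < 2L) abort("need at least 2 subjects")
  time <- subject_rdms[[1]]$time
  win <- which(time >= window_ms[1] & time <= window_ms[2])
  if (!length(win)) abort("window lies outside the time axis")

  a <- rdv(models$task)
  b <- rdv(models$category)
  precomp <- fusion_precompute(list(rdv(fmri_rdm)), a, b)
  n_pair <- ncol(subject_rdms[[1]]$rdv)
  stack <- lapply(subject_rdms, function(s) s$rdv[win, , drop = FALSE])

  stat_curve <- function(avg_rdv) {
    r <- (rank_z_rows(avg_rdv) %*% precomp[[1]] / (n_pair - 1))^2
    switch(statistic,
           r2_total = r[, "y"],
           c_task = r[, "yb"] - r[, "yab"],
           c_category = r[, "ya"] - r[, "yab"])
  }

  estimate_curve <- stat_curve(Reduce(`+`, stack) / n)
  estimate <- latency_stat(estimate_curve, time[win], seq_along(win), mode,
                           onset_criterion)

  stat <- with_seed(derive_seed(seed, "fboot"), function() {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      avg <- Reduce(`+`, stack[idx]) / n
      latency_stat(stat_curve(avg), time[win], seq_along(win), mode,
                   onset_criterion)
    }, 1.0)
  })

  ci <- quantile(stat, c(0.025, 0.975), na.rm = TRUE, type = 1, names = FALSE)
  structure(
    list(estimate = estimate, lower = ci[1], upper = ci[2], mode = mode,
         n_boot = n_boot, window_ms = window_ms, seed = seed,
         flat_window = length(unique(estimate_curve)) == 1L,
         n_failed = sum(is.na(stat)), boot = stat, statistic = statistic),
    class = "peak_ci")
}
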
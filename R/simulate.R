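#' Ground-truth signal structure for synthetic epochs
#'
#' Describes the latent signal injected into synthetic epochs: a task-specific
#' spatial pattern switched on at `task_onset_ms` after cue onset, and a
#' category-specific spatial pattern switched on at `object_onset_ms` after
#' stimulus onset, each weighted by a nonnegative amplitude envelope. For
#' conceptual tasks the object pattern is additionally scaled by
#' `tasktype_gain` from `tasktype_gain_onset_ms` after stimulus onset, which
#' emulates a late task-type modulation of object signal strength without
#' changing pattern geometry.
#'
#' Default envelopes are boxcars with a short sigmoidal edge
#' (`edge_ms`). Any nonnegative function of time (ms) can be supplied instead
#' via `task_envelope` / `object_envelope`; these receive time relative to cue
#' and stimulus onset respectively.
#'
#' @param task_onset_ms Task pattern onset, ms after cue onset.
#' @param object_onset_ms Object pattern onset, ms after stimulus onset.
#' @param task_amplitude,object_amplitude Peak envelope amplitudes (signal
#'   units per unit pattern).
#' @param task_duration_ms,object_duration_ms Envelope durations. Both
#'   default to transient responses (600 ms for the task cue, 1400 ms for
#'   the object, which stays informative until the response screen): evoked
#'   information rises quickly and decays rather than persisting at constant
#'   strength, and a near-DC envelope spanning the whole epoch would not
#'   survive the 0.1 Hz high-pass of the preprocessing chain.
#' @param edge_ms Standard deviation of the sigmoidal boxcar edge; 0 gives a
#'   hard boxcar.
#' @param tasktype_gain Multiplier on the object pattern during conceptual
#'   tasks (1 = no task-type effect).
#' @param tasktype_gain_onset_ms Onset of the gain, ms after stimulus onset.
#' @param task_envelope,object_envelope Optional custom envelope functions.
#' @param pattern_seed Seed for the per-subject spatial patterns.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(task_onset_ms = 100, object_onset_ms = 80,
                         task_amplitude = 0.06, object_amplitude = 0.06,
                         task_duration_ms = 600, object_duration_ms = 1400,
                         edge_ms = 5, tasktype_gain = 1,
                         tasktype_gain_onset_ms = 400,
                         task_envelope = NULL, object_envelope = NULL,
                         pattern_seed = 1L) {
  check_scalar(task_amplitude, "task_amplitude", min = 0)
  check_scalar(object_amplitude, "object_amplitude", min = 0)
  check_scalar(tasktype_gain, "tasktype_gain", min = 0)
  check_scalar(edge_ms, "edge_ms", min = 0)
  structure(
    list(task_onset_ms = task_onset_ms, object_onset_ms = object_onset_ms,
         task_amplitude = task_amplitude, object_amplitude = object_amplitude,
         task_duration_ms = task_duration_ms,
         object_duration_ms = object_duration_ms, edge_ms = edge_ms,
         tasktype_gain = tasktype_gain,
         tasktype_gain_onset_ms = tasktype_gain_onset_ms,
         task_envelope = task_envelope, object_envelope = object_envelope,
         pattern_seed = as.integer(pattern_seed)),
    class = "ground_truth")
}

# soft-edged boxcar; edge = 0 degenerates to a hard boxcar
boxcar_envelope <- function(t, onset, duration, amplitude, edge) {
  if (edge <= 0) {
    amplitude * as.double(t >= onset & t < onset + duration)
  } else {
    amplitude * stats::pnorm(t, onset, edge) *
      stats::pnorm(onset + duration - t, 0, edge)
  }
}

eval_envelope <- function(fn, t, onset, duration, amplitude, edge) {
  env <- if (is.null(fn)) {
    boxcar_envelope(t, onset, duration, amplitude, edge)
  } else {
    as.double(fn(t))
  }
  if (any(env < -1e-12)) abort("amplitude envelopes must be nonnegative")
  pmax(env, 0)
}

#' Simulate epoched sensor data for one subject
#'
#' Each trial is the sum of a task-specific spatial pattern weighted by the
#' task envelope (time-locked to cue onset at 0 ms), a category-specific
#' spatial pattern weighted by the object envelope (time-locked to stimulus
#' onset) and, for conceptual tasks, the task-type gain, plus white Gaussian
#' sensor noise. Spatial patterns are standard-normal vectors drawn once per
#' subject from `truth$pattern_seed` combined with the subject id; noise is
#' drawn from `seed`. Identical seeds give bit-identical output.
#'
#' @param design Trial table from [generate_design()].
#' @param truth A [ground_truth()].
#' @param n_channels Number of sensors (>= 2).
#' @param sampling_rate Sampling rate in Hz.
#' @param noise_sd Standard deviation of the additive sensor noise (>= 0).
#' @param seed Integer seed for the noise.
#' @param subject Subject identifier (also folded into the pattern seed).
#' @param epoch_ms Epoch limits in ms relative to cue onset.
#' @param stimulus_onset_ms Stimulus onset in ms.
#' @return An [new_epochs()] object with ground-truth metadata in
#'   `provenance$truth`.
#' @export
generate_subject_epochs <- function(design, truth = ground_truth(),
                                    n_channels = 64, sampling_rate = 300,
                                    noise_sd = 1, seed = 1L,
                                    subject = "s01",
                                    epoch_ms = c(-100, 5000),
                                    stimulus_onset_ms = 2000) {
  n_channels <- check_count(n_channels, "n_channels", min = 2L)
  check_scalar(noise_sd, "noise_sd", min = 0)
  if (truth$task_onset_ms < epoch_ms[1] || truth$task_onset_ms > epoch_ms[2]) {
    abort("task pattern onset lies outside the epoch")
  }
  obj_abs <- stimulus_onset_ms + truth$object_onset_ms
  if (obj_abs < epoch_ms[1] || obj_abs > epoch_ms[2]) {
    abort("object pattern onset lies outside the epoch")
  }

  n_time <- round((epoch_ms[2] - epoch_ms[1]) / 1000 * sampling_rate)
  time <- epoch_ms[1] + (seq_len(n_time) - 1L) * 1000 / sampling_rate

  tasks <- unique(design$task)
  cats <- unique(design$category)
  patterns <- with_seed(
    derive_seed(truth$pattern_seed, "patterns", subject), function() {
      list(task = matrix(rnorm(n_channels * length(tasks)), n_channels,
                         dimnames = list(NULL, tasks)),
           category = matrix(rnorm(n_channels * length(cats)), n_channels,
                             dimnames = list(NULL, cats)))
    })

  env_task <- eval_envelope(truth$task_envelope, time, truth$task_onset_ms,
                            truth$task_duration_ms, truth$task_amplitude,
                            truth$edge_ms)
  t_obj <- time - stimulus_onset_ms
  env_obj <- eval_envelope(truth$object_envelope, t_obj,
                           truth$object_onset_ms, truth$object_duration_ms,
                           truth$object_amplitude, truth$edge_ms)
  gain <- 1 + (truth$tasktype_gain - 1) *
    as.double(t_obj >= truth$tasktype_gain_onset_ms)
  env_obj_gained <- env_obj * gain

  n_trials <- nrow(design)
  data <- with_seed(derive_seed(seed, "noise", subject), function() {
    if (noise_sd > 0) {
      array(rnorm(n_trials * n_channels * n_time, sd = noise_sd),
            dim = c(n_trials, n_channels, n_time))
    } else {
      array(0, dim = c(n_trials, n_channels, n_time))
    }
  })

  conceptual <- !is.na(design$task_type) & design$task_type == "conceptual"
  if (any(env_task != 0) || any(env_obj != 0)) {
    for (i in seq_len(n_trials)) {
      sig <- tcrossprod(patterns$task[, design$task[i]], env_task) +
        tcrossprod(patterns$category[, design$category[i]],
                   if (conceptual[i]) env_obj_gained else env_obj)
      data[i, , ] <- data[i, , ] + sig
    }
  }

  new_epochs(data, time, sampling_rate, design, subject = subject,
             provenance = list(
               truth = truth, seed = seed, noise_sd = noise_sd,
               stimulus_onset_ms = stimulus_onset_ms,
               patterns = patterns))
}

# Sylvester-construction Hadamard basis: n must be a power of two. Columns
# are +-1 vectors that are exactly orthogonal and (beyond the first,
# constant, column) exactly zero-sum in floating point, which keeps the
# induced dissimilarity structure of noise-free synthetic patterns exactly
# tied where the models say it should be.
hadamard_basis <- function(n) {
  h <- matrix(1, 1, 1)
  while (nrow(h) < n) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

#' Synthesize fMRI-like ROI condition patterns
#'
#' Builds, per region of interest, a 32 x `n_units` condition pattern matrix
#' (task-major condition order) whose induced 1 - Pearson dissimilarity
#' structure mixes the binary task model and category model in proportion to
#' the squared weights, plus independent Gaussian unit noise. Each task and
#' each category is assigned its own basis pattern; the basis patterns are
#' distinct non-constant columns of a seeded, randomly row-permuted and
#' sign-flipped Hadamard matrix, hence zero-mean, unit-variance and exactly
#' mutually orthogonal. With `noise_sd = 0` the induced dissimilarities are
#' therefore exact: `1 - task_weight^2 / (task_weight^2 + object_weight^2)`
#' for two conditions sharing only a task, symmetrically for a shared
#' category, and exactly 1 when they share neither. Off-diagonal
#' dissimilarity under pure noise is approximately 1 (independent patterns).
#'
#' @param task_weight,object_weight,noise_sd Nonnegative mixing weights and
#'   noise standard deviation; vectors are recycled across ROIs.
#' @param n_units Pattern dimensionality per ROI; a power of two at least
#'   `n_tasks + n_categories + 1` (Hadamard construction).
#' @param seed Integer seed.
#' @param roi_names Names of the regions; defaults to `roi1`, `roi2`, ...
#' @param tasks,categories Condition labels (canonical design by default).
#' @return An object of class `roi_pattern_set`: named list of pattern
#'   matrices with `condition_order` and `weights` metadata.
#' @export
generate_fmri_patterns <- function(task_weight = 1, object_weight = 1,
                                   noise_sd = 0.5, n_units = 256,
                                   seed = 1L, roi_names = NULL,
                                   tasks = task_levels(4),
                                   categories = category_levels(8)) {
  n_roi <- max(length(task_weight), length(object_weight), length(noise_sd))
  task_weight <- rep_len(task_weight, n_roi)
  object_weight <- rep_len(object_weight, n_roi)
  noise_sd <- rep_len(noise_sd, n_roi)
  if (any(task_weight < 0) || any(object_weight < 0) || any(noise_sd < 0)) {
    abort("weights and noise_sd must be nonnegative")
  }
  n_units <- check_count(n_units, "n_units", min = 2L)
  n_basis <- length(tasks) + length(categories)
  if (bitwAnd(n_units, n_units - 1L) != 0L || n_units <= n_basis) {
    abort(sprintf("`n_units` must be a power of two larger than %d", n_basis))
  }
  if (is.null(roi_names)) roi_names <- sprintf("roi%d", seq_len(n_roi))

  condition_order <- tidyr::expand_grid(task = tasks, category = categories)

  patterns <- with_seed(derive_seed(seed, "fmri"), function() {
    had <- hadamard_basis(n_units)
    setNames(lapply(seq_len(n_roi), function(r) {
      cols <- 1L + sample.int(n_units - 1L, n_basis)  # skip constant column
      basis <- had[sample.int(n_units), cols, drop = FALSE] *
        rep(sample(c(-1, 1), n_basis, replace = TRUE), each = n_units)
      task_basis <- basis[, seq_along(tasks), drop = FALSE]
      cat_basis <- basis[, length(tasks) + seq_along(categories),
                         drop = FALSE]
      p <- task_weight[r] *
        t(task_basis[, match(condition_order$task, tasks)]) +
        object_weight[r] *
          t(cat_basis[, match(condition_order$category, categories)])
      if (noise_sd[r] > 0) {
        p <- p + noise_sd[r] *
          matrix(rnorm(nrow(condition_order) * n_units),
                 nrow(condition_order))
      }
      rownames(p) <- paste(condition_order$task, condition_order$category,
                           sep = ".")
      p
    }), roi_names)
  })

  structure(
    list(patterns = patterns, condition_order = condition_order,
         weights = tibble(roi = roi_names, task_weight = task_weight,
                          object_weight = object_weight,
                          noise_sd = noise_sd),
         seed = as.integer(seed)),
    class = "roi_pattern_set")
}

#' @export
print.roi_pattern_set <- function(x, ...) {
  cat(sprintf("<roi_pattern_set> %d ROIs x %d conditions x %d units\n",
              length(x$patterns), nrow(x$condition_order),
              ncol(x$patterns[[1]])))
  print(x$weights)
  invisible(x)
}
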
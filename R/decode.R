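#' Decoding configuration
#'
#' @param supertrial_size Trials averaged per supertrial (without
#'   replacement).
#' @param n_iterations Number of supertrial/partition iterations averaged
#'   into the final accuracy estimate.
#' @param C Regularization constant of the linear max-margin classifier.
#' @param label_factor Which trial factor to decode: `"category"` (28
#'   pairwise problems in the canonical design) or `"task"` (6 problems).
#' @param seed Integer seed; per-iteration streams are derived from
#'   `(seed, iteration)` so iterations are independent and reproducible.
#' @return An object of class `decoding_config`.
#' @export
decoding_config <- function(supertrial_size = 10, n_iterations = 500, C = 1,
                            label_factor = c("category", "task"),
                            seed = 1L) {
  structure(
    list(supertrial_size = check_count(supertrial_size, "supertrial_size"),
         n_iterations = check_count(n_iterations, "n_iterations"),
         C = check_scalar(C, "C", min = 1e-12),
         label_factor = match.arg(label_factor),
         seed = as.integer(seed)),
    class = "decoding_config")
}

# canonical baseline window per decoded factor; decoding refuses provenance
# that records a mismatching normalization window
expected_baseline <- function(label_factor) {
  switch(label_factor,
         task = c(-100, 0),
         category = c(1900, 2000),
         abort(sprintf("no canonical baseline window for factor `%s`",
                       label_factor)))
}

check_baseline_provenance <- function(dataset, label_factor) {
  bw <- dataset$provenance$baseline$window_ms
  if (is.null(bw)) return(invisible(TRUE))
  want <- expected_baseline(label_factor)
  if (!isTRUE(all.equal(as.double(bw), as.double(want)))) {
    abort(sprintf(
      "dataset was baseline-normalized on [%g, %g] ms but %s decoding expects [%g, %g] ms",
      bw[1], bw[2], label_factor, want[1], want[2]))
  }
  invisible(TRUE)
}

#' Build supertrials by averaging same-class trials without replacement
#'
#' Trials of each class are shuffled (seeded) and split into disjoint groups
#' of `group_size`; each group's average is one supertrial. Leftover trials
#' (fewer than `group_size`) are unused in this draw. Catch trials are
#' excluded.
#'
#' @param dataset Component `epochs`.
#' @param label_factor Column of the trial table defining classes.
#' @param group_size Trials per supertrial.
#' @param rng_seed Seed for the shuffling.
#' @return A `supertrial_set`: array `data` (supertrials x components x
#'   time), `class` labels, `mapping` of source trials, and metadata.
#' @export
make_supertrials <- function(dataset, label_factor = "category",
                             group_size = 10, rng_seed = 1L) {
  plan <- supertrial_plan(dataset, label_factor, group_size, rng_seed)
  cube <- cpp_supertrials(dataset$data, plan$group_id, plan$n_super,
                          group_size)
  data <- aperm(cube[-dim(cube)[1], , , drop = FALSE], c(2L, 1L, 3L))
  structure(
    list(data = data, class = plan$cls, mapping = plan$mapping,
         factor = label_factor, group_size = group_size,
         time = dataset$time),
    class = "supertrial_set")
}

# seeded assignment of trials to disjoint supertrial groups; catch trials and
# leftovers stay in group 0 and never enter the averages
supertrial_plan <- function(dataset, label_factor, group_size, rng_seed) {
  stopifnot(inherits(dataset, "epochs"))
  labels <- dataset$trials[[label_factor]]
  if (is.null(labels)) abort(sprintf("no `%s` column in trials", label_factor))
  eligible <- if ("is_catch" %in% names(dataset$trials)) {
    !dataset$trials$is_catch
  } else {
    rep(TRUE, nrow(dataset$trials))
  }
  classes <- sort(unique(labels[eligible]))
  counts <- table(labels[eligible])
  if (any(counts < group_size)) {
    abort(sprintf(
      "class(es) %s have fewer trials than the supertrial size %d",
      paste(names(counts)[counts < group_size], collapse = ", "),
      group_size))
  }
  with_seed(rng_seed, function() {
    mapping <- list()
    cls <- character()
    group_id <- integer(nrow(dataset$trials))
    first_of_class <- integer(length(classes))
    n_super <- 0L
    for (k in seq_along(classes)) {
      idx <- sample(which(eligible & labels == classes[k]))
      n_groups <- floor(length(idx) / group_size)
      first_of_class[k] <- n_super + 1L
      for (g in seq_len(n_groups)) {
        n_super <- n_super + 1L
        members <- idx[((g - 1L) * group_size + 1L):(g * group_size)]
        group_id[members] <- n_super
        mapping[[n_super]] <- members
        cls[n_super] <- classes[k]
      }
    }
    list(group_id = group_id, mapping = mapping, cls = cls,
         classes = classes, first_of_class = first_of_class,
         n_super = n_super)
  })
}

#' Ordering accuracy of a pair of decision values
#'
#' Given one held-out sample per class of a two-class problem, scores 100 if
#' the positive-class sample received the larger decision value, 0 if the
#' order is reversed, and 50 on a tie. For one sample per class this equals
#' the two-sample area under the ROC curve and is independent of the
#' classifier's bias term.
#'
#' @param decision_values Length-2 numeric: decision values of the two test
#'   samples.
#' @param true_classes Length-2 labels of those samples.
#' @param positive_class The classifier's positive class; defaults to the
#'   lexicographically first of `true_classes`.
#' @return Accuracy in percent: 0, 50, or 100.
#' @export
ordering_accuracy <- function(decision_values, true_classes,
                              positive_class = sort(true_classes)[1]) {
  stopifnot(length(decision_values) == 2L, length(true_classes) == 2L,
            length(unique(true_classes)) == 2L)
  dv_pos <- decision_values[true_classes == positive_class]
  dv_neg <- decision_values[true_classes != positive_class]
  if (dv_pos > dv_neg) 100 else if (dv_pos < dv_neg) 0 else 50
}

# lexicographically first class of each pair is the positive class
class_pairs <- function(classes) {
  classes <- sort(classes)
  utils::combn(classes, 2L)
}

# one iteration: supertrials, one held out per class, rest training;
# supertrials land directly in the (features+bias) x instance x time layout
# the compiled decoders expect
iteration_split <- function(dataset, label_factor, group_size, rng_seed) {
  plan <- supertrial_plan(dataset, label_factor, group_size, rng_seed)
  cube <- cpp_supertrials(dataset$data, plan$group_id, plan$n_super,
                          group_size)
  test_idx <- plan$first_of_class
  train_idx <- setdiff(seq_len(plan$n_super), test_idx)
  list(
    train = cube[, train_idx, , drop = FALSE],
    train_cls = match(plan$cls[train_idx], plan$classes) - 1L,
    test = cube[, test_idx, , drop = FALSE],
    test_cls = match(plan$cls[test_idx], plan$classes) - 1L,
    classes = plan$classes)
}

# run `fn(train, train_cls, test, test_cls, pairs)` for every iteration seed
# and average
run_iterations <- function(dataset, label_factor, group_size, seeds, fn) {
  acc <- 0
  for (s in seeds) {
    sp <- iteration_split(dataset, label_factor, group_size, s)
    pairs <- matrix(match(class_pairs(sp$classes), sp$classes) - 1L, 2L)
    acc <- acc + fn(sp$train, sp$train_cls, sp$test, sp$test_cls, pairs)
  }
  acc / length(seeds)
}

new_accuracy_timecourse <- function(time, accuracy, factor, config, subject,
                                    chance = 50) {
  structure(
    list(time = time, accuracy = accuracy, chance = chance, factor = factor,
         config = config, subject = subject),
    class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf(
    "<decoding_timecourse> %s decoding, subject %s: %d time points, mean %.1f%% (chance %.0f%%)\n",
    x$factor, x$subject %||% "?", length(x$time), mean(x$accuracy), x$chance))
  invisible(x)
}

#' Time-resolved pairwise decoding
#'
#' At every time point and for every unordered pair of classes, a linear
#' max-margin classifier (regularization `C`) is trained on supertrial
#' patterns with one supertrial per class held out, and scored with
#' [ordering_accuracy()] on the held-out pair. Accuracies are averaged over
#' pairs (28 for 8 categories, 6 for 4 tasks; chance 50%) and over
#' `n_iterations` re-randomized supertrial draws.
#'
#' @param dataset Preprocessed component `epochs` with trial labels.
#' @param config A [decoding_config()].
#' @return A `decoding_timecourse` (see [tidy.decoding_timecourse()]).
#' @export
decode_timecourse <- function(dataset, config = decoding_config()) {
  stopifnot(inherits(dataset, "epochs"))
  check_baseline_provenance(dataset, config$label_factor)
  seeds <- vapply(seq_len(config$n_iterations),
                  function(it) derive_seed(config$seed, "iter", it), 1L)
  acc <- run_iterations(
    dataset, config$label_factor, config$supertrial_size, seeds,
    function(train, train_cls, test, test_cls, pairs) {
      cpp_decode_timecourse(train, train_cls, test, test_cls, pairs,
                            config$C)
    })
  new_accuracy_timecourse(dataset$time, as.double(acc),
                          config$label_factor, config, dataset$subject)
}

#' Temporal generalization of decoding
#'
#' Trains the per-pair classifiers of [decode_timecourse()] at every training
#' time point and evaluates each on the same held-out supertrials at every
#' testing time point, yielding a train-time x test-time accuracy matrix
#' averaged over pairs and iterations. The diagonal corresponds to matched
#' train/test times.
#'
#' @param dataset Preprocessed component `epochs`.
#' @param config A [decoding_config()].
#' @param time_step Evaluate every `time_step`-th sample on both axes (1 =
#'   full resolution).
#' @return A `tempgen_matrix` with fields `accuracy` (train x test),
#'   `train_time`, `test_time`.
#' @export
temporal_generalization <- function(dataset, config = decoding_config(),
                                    time_step = 1L) {
  stopifnot(inherits(dataset, "epochs"))
  check_baseline_provenance(dataset, config$label_factor)
  if (time_step > 1L) {
    keep <- seq(1L, length(dataset$time), by = time_step)
    dataset$data <- dataset$data[, , keep, drop = FALSE]
    dataset$time <- dataset$time[keep]
    dataset$sampling_rate <- dataset$sampling_rate / time_step
  }
  seeds <- vapply(seq_len(config$n_iterations),
                  function(it) derive_seed(config$seed, "iter", it), 1L)
  acc <- run_iterations(
    dataset, config$label_factor, config$supertrial_size, seeds,
    function(train, train_cls, test, test_cls, pairs) {
      cpp_decode_tempgen(train, train_cls, test, test_cls, pairs, config$C)
    })
  structure(
    list(accuracy = acc, train_time = dataset$time,
         test_time = dataset$time, chance = 50, factor = config$label_factor,
         config = config, subject = dataset$subject),
    class = "tempgen_matrix")
}

#' @export
print.tempgen_matrix <- function(x, ...) {
  cat(sprintf(
    "<tempgen_matrix> %s decoding, subject %s: %d x %d times, mean %.1f%%\n",
    x$factor, x$subject %||% "?", length(x$train_time), length(x$test_time),
    mean(x$accuracy)))
  invisible(x)
}

#' Object decoding within and between task types
#'
#' Object-category classifiers are trained on supertrials from one task type
#' (perceptual: Color/Tilt; conceptual: Content/Size) and tested on held-out
#' supertrials either from the same task type (within) or from the other task
#' type (between), averaging over both directions and iterations. Equal
#' within- and between-type accuracy indicates that task type changes at most
#' the strength, not the geometry, of object patterns.
#'
#' @param dataset Preprocessed component `epochs` whose trial table has
#'   `task_type` and `category` columns.
#' @param config A [decoding_config()] (its `label_factor` is ignored;
#'   categories are decoded).
#' @return List with elements `within` and `between`, both
#'   `decoding_timecourse` objects.
#' @export
cross_tasktype_object_decode <- function(dataset, config = decoding_config()) {
  stopifnot(inherits(dataset, "epochs"))
  check_baseline_provenance(dataset, "category")
  dataset <- epochs_experimental(dataset)
  if (!"task_type" %in% names(dataset$trials) ||
      anyNA(dataset$trials$task_type)) {
    abort("trial table must define `task_type` for all trials")
  }
  types <- c("perceptual", "conceptual")
  sub <- lapply(types, function(tt) {
    epochs_subset_trials(dataset, which(dataset$trials$task_type == tt))
  })
  names(sub) <- types

  within <- 0
  between <- 0
  for (it in seq_len(config$n_iterations)) {
    sp <- lapply(types, function(tt) {
      iteration_split(sub[[tt]], "category", config$supertrial_size,
                      derive_seed(config$seed, "iter", it, tt))
    })
    names(sp) <- types
    classes <- sp[[1]]$classes
    if (!identical(classes, sp[[2]]$classes)) {
      abort("task types do not share the same category classes")
    }
    pairs <- matrix(match(class_pairs(classes), classes) - 1L, 2L)
    for (tr in types) {
      te_other <- setdiff(types, tr)
      within <- within +
        cpp_decode_timecourse(sp[[tr]]$train, sp[[tr]]$train_cls,
                              sp[[tr]]$test, sp[[tr]]$test_cls, pairs,
                              config$C)
      between <- between +
        cpp_decode_timecourse(sp[[tr]]$train, sp[[tr]]$train_cls,
                              sp[[te_other]]$test, sp[[te_other]]$test_cls,
                              pairs, config$C)
    }
  }
  denom <- 2 * config$n_iterations
  list(
    within = new_accuracy_timecourse(dataset$time, as.double(within) / denom,
                                     "category (within task type)", config,
                                     dataset$subject),
    between = new_accuracy_timecourse(dataset$time,
                                      as.double(between) / denom,
                                      "category (between task types)",
                                      config, dataset$subject))
}
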
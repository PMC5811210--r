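#' Specify the factorial task x object design
#'
#' The default design crosses 4 tasks (two perceptual: Color, Tilt; two
#' conceptual: Content, Size) with 8 object categories, 5 exemplars, 2 outline
#' colors and 2 tilts, giving 8 x 5 x 2 x 2 = 160 unique stimuli. Each unique
#' stimulus appears once per task, so the default yields 640 experimental
#' trials, distributed over 20 runs of 32 experimental plus 4 catch trials.
#'
#' @param n_tasks,n_categories,n_exemplars,n_colors,n_tilts Factor level
#'   counts.
#' @param n_runs Number of runs.
#' @param trials_per_run Total trials per run (experimental + catch).
#' @param catch_per_run Catch trials per run.
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' spec <- design_spec()
#' spec$n_experimental  # 640
design_spec <- function(n_tasks = 4, n_categories = 8, n_exemplars = 5,
                        n_colors = 2, n_tilts = 2, n_runs = 20,
                        trials_per_run = 36, catch_per_run = 4) {
  n_tasks <- check_count(n_tasks, "n_tasks")
  n_categories <- check_count(n_categories, "n_categories")
  n_exemplars <- check_count(n_exemplars, "n_exemplars")
  n_colors <- check_count(n_colors, "n_colors")
  n_tilts <- check_count(n_tilts, "n_tilts")
  n_runs <- check_count(n_runs, "n_runs")
  trials_per_run <- check_count(trials_per_run, "trials_per_run")
  catch_per_run <- check_count(catch_per_run, "catch_per_run", min = 0L)
  if (catch_per_run >= trials_per_run) {
    abort("`catch_per_run` must be smaller than `trials_per_run`")
  }

  experimental_per_run <- trials_per_run - catch_per_run
  n_unique <- n_categories * n_exemplars * n_colors * n_tilts
  n_experimental <- n_unique * n_tasks
  if (n_runs * experimental_per_run != n_experimental) {
    abort(sprintf(
      paste0("design error: %d runs x %d experimental trials/run = %d does ",
             "not match %d unique stimuli x %d tasks = %d"),
      n_runs, experimental_per_run, n_runs * experimental_per_run,
      n_unique, n_tasks, n_experimental))
  }

  structure(
    list(n_tasks = n_tasks, n_categories = n_categories,
         n_exemplars = n_exemplars, n_colors = n_colors, n_tilts = n_tilts,
         n_runs = n_runs, trials_per_run = trials_per_run,
         catch_per_run = catch_per_run,
         experimental_per_run = experimental_per_run,
         n_unique_stimuli = n_unique, n_experimental = n_experimental,
         n_catch = n_runs * catch_per_run,
         task_levels = task_levels(n_tasks),
         category_levels = category_levels(n_categories)),
    class = "design_spec")
}

# canonical labels; generic labels for non-default designs
task_levels <- function(n) {
  if (n == 4L) c("color", "tilt", "content", "size")
  else sprintf("task%02d", seq_len(n))
}

category_levels <- function(n) {
  if (n == 8L) {
    c("butterfly", "cow", "dresser", "flower",
      "motorbike", "skate", "tree", "vase")
  } else {
    sprintf("cat%02d", seq_len(n))
  }
}

# perceptual tasks probe low-level image features, conceptual tasks semantic
# properties; only defined for the canonical 4-task design
task_type_of <- function(task) {
  type <- rep(NA_character_, length(task))
  type[task %in% c("color", "tilt")] <- "perceptual"
  type[task %in% c("content", "size")] <- "conceptual"
  type
}

#' Generate a randomized trial table
#'
#' Produces one trial per row: every unique stimulus (category x exemplar x
#' color x tilt) is shown exactly once in each task context among experimental
#' trials, in seeded random order, split into runs. Catch trials (shortened
#' post-stimulus delay in the experiment; flagged here and excluded from
#' analyses by default) are random task/stimulus combinations interspersed in
#' every run.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed controlling the randomization.
#' @return A tibble with columns `trial`, `run`, `task`, `task_type`,
#'   `category`, `exemplar`, `color`, `tilt`, `is_catch`.
#' @export
#' @examples
#' design <- generate_design(design_spec(), seed = 1)
#' sum(!design$is_catch)  # 640
generate_design <- function(spec = design_spec(), seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(derive_seed(seed, "design"), function() {
    experimental <- tidyr::expand_grid(
      task = spec$task_levels,
      category = spec$category_levels,
      exemplar = seq_len(spec$n_exemplars),
      color = seq_len(spec$n_colors),
      tilt = seq_len(spec$n_tilts))
    experimental <- experimental[sample.int(nrow(experimental)), ]
    experimental$is_catch <- FALSE
    experimental$run <- rep(seq_len(spec$n_runs),
                            each = spec$experimental_per_run)

    n_catch <- spec$n_catch
    catch <- tibble(
      task = sample(spec$task_levels, n_catch, replace = TRUE),
      category = sample(spec$category_levels, n_catch, replace = TRUE),
      exemplar = sample.int(spec$n_exemplars, n_catch, replace = TRUE),
      color = sample.int(spec$n_colors, n_catch, replace = TRUE),
      tilt = sample.int(spec$n_tilts, n_catch, replace = TRUE),
      is_catch = TRUE,
      run = if (n_catch > 0) rep(seq_len(spec$n_runs),
                                 each = spec$catch_per_run) else integer())

    trials <- dplyr::bind_rows(experimental, catch)
    trials <- trials[order(trials$run, sample.int(nrow(trials))), ]
    trials$trial <- seq_len(nrow(trials))
    trials$task_type <- task_type_of(trials$task)
    dplyr::select(trials, "trial", "run", "task", "task_type", "category",
                  "exemplar", "color", "tilt", "is_catch")
  })
}
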
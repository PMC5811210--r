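# Small factorial designs and epoch fixtures shared across tests.

# 4 tasks x 2 categories, one stimulus each: 8 experimental trials per
# repetition of the design
small_spec <- function(n_runs = 2, trials_per_run = 5, catch_per_run = 1) {
  design_spec(n_tasks = 4, n_categories = 2, n_exemplars = 1, n_colors = 1,
              n_tilts = 1, n_runs = n_runs, trials_per_run = trials_per_run,
              catch_per_run = catch_per_run)
}

# free-form trial table (bypasses run arithmetic) for decoding fixtures
make_trials <- function(n_per_cell = 2, tasks = c("color", "tilt", "content",
                                                  "size"),
                        categories = c("catA", "catB")) {
  tr <- tidyr::expand_grid(task = tasks, category = categories,
                           rep = seq_len(n_per_cell))
  tr$trial <- seq_len(nrow(tr))
  tr$run <- 1L
  tr$exemplar <- 1L
  tr$color <- 1L
  tr$tilt <- 1L
  tr$is_catch <- FALSE
  tr$task_type <- ifelse(tr$task %in% c("color", "tilt"), "perceptual",
                         ifelse(tr$task %in% c("content", "size"),
                                "conceptual", NA))
  tr[, c("trial", "run", "task", "task_type", "category", "exemplar",
         "color", "tilt", "is_catch")]
}

# epochs with user-supplied per-trial signal builder; default pure noise
make_test_epochs <- function(trials, n_channels = 8, sampling_rate = 60,
                             noise_sd = 1, seed = 1,
                             signal_fn = NULL) {
  n_time <- round(5.1 * sampling_rate)
  time <- -100 + (seq_len(n_time) - 1) * 1000 / sampling_rate
  set.seed(seed)
  data <- array(rnorm(nrow(trials) * n_channels * n_time, sd = noise_sd),
                dim = c(nrow(trials), n_channels, n_time))
  if (!is.null(signal_fn)) {
    for (i in seq_len(nrow(trials))) {
      data[i, , ] <- data[i, , ] + signal_fn(trials[i, ], time, n_channels)
    }
  }
  new_epochs(data, time, sampling_rate, trials, subject = "t01")
}

# deterministic class patterns for separability fixtures
class_pattern <- function(label, n_channels) {
  set.seed(sum(utf8ToInt(as.character(label))))
  rnorm(n_channels)
}

# evaluate a heavy computation in a forked child (where available) so its
# memory returns to the OS instead of fragmenting the test process heap
with_fork <- function(fn) {
  if (.Platform$OS.type != "unix") return(fn())
  job <- parallel::mcparallel(fn())
  out <- parallel::mccollect(job)[[1]]
  if (inherits(out, "try-error") || is.null(out)) {
    stop("forked computation failed: ", paste(as.character(out),
                                              collapse = " "))
  }
  out
}

# cached full desk-preset pipeline run, shared by the acceptance tests that
# exercise parameter recovery and the end-to-end budget
the_test_cache <- new.env(parent = emptyenv())

desk_pipeline_fixture <- function() {
  if (is.null(the_test_cache$desk)) {
    out_dir <- file.path(tempdir(), "repdyn-desk-run")
    cfg <- pipeline_config("desk", seed = 1, out_dir = out_dir,
                           overrides = list(io = list(verbose = FALSE)))
    t0 <- Sys.time()
    bundle <- run_pipeline(cfg)
    minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
    the_test_cache$desk <- list(bundle = bundle, minutes = minutes,
                                config = cfg)
  }
  the_test_cache$desk
}
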
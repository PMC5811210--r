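default_pipeline_config <- function(preset) {
  common <- list(
    preset = preset, seed = 1L, out_dir = "repdyn-results",
    design = list(),
    truth = list(task_onset_ms = 100, object_onset_ms = 80,
                 task_amplitude = 0.06, object_amplitude = 0.06,
                 tasktype_gain = 1),
    fmri = list(
      roi_names = c("EVC", "LO", "pFS", "lPFC", "PPC"),
      task_weight = c(0.4, 0.6, 0.8, 1.0, 1.0),
      object_weight = c(1.0, 1.0, 0.8, 0.3, 0.3),
      noise_sd = 0.5, n_units = 256),
    stats = list(alpha = 0.05, max_exhaustive = 2^17,
                 task_window = c(0, 3500), object_window = c(2000, 3500),
                 task_peak_window = c(0, 2000),
                 object_peak_window = c(2000, 3500)),
    io = list(write_epochs = FALSE, verbose = TRUE))
  scale <- if (preset == "desk") {
    list(simulate = list(n_subjects = 10, n_channels = 64,
                         sampling_rate = 300, noise_sd = 1),
         preprocess = list(band = c(0.1, 100), notch = 60,
                           variance_drop_fraction = 0.01,
                           max_drop_fraction = 0.5, hdhm_ms = 15,
                           target_rate = 100),
         decoding = list(supertrial_size = 10, n_iterations = 20, C = 1),
         cross = list(n_iterations = 10),
         tempgen = list(n_iterations = 10, time_step = 5),
         stats_scale = list(n_perm_2d = 2000, n_perm_fusion = 1000,
                            n_boot_decoding = 10000, n_boot_fusion = 1000))
  } else {
    list(simulate = list(n_subjects = 17, n_channels = 272,
                         sampling_rate = 1200, noise_sd = 1),
         preprocess = list(band = c(0.1, 300), notch = 60,
                           variance_drop_fraction = 0.01,
                           max_drop_fraction = 0.5, hdhm_ms = 15,
                           target_rate = 120),
         decoding = list(supertrial_size = 10, n_iterations = 500, C = 1),
         cross = list(n_iterations = 500),
         tempgen = list(n_iterations = 500, time_step = 1),
         stats_scale = list(n_perm_2d = 10000, n_perm_fusion = 5000,
                            n_boot_decoding = 100000, n_boot_fusion = 5000))
  }
  common$simulate <- scale$simulate
  common$preprocess <- scale$preprocess
  common$decoding <- scale$decoding
  common$cross <- scale$cross
  common$tempgen <- scale$tempgen
  common$stats <- c(common$stats, scale$stats_scale)
  common
}

merge_config <- function(defaults, overrides, path = "") {
  for (nm in names(overrides)) {
    here <- if (path == "") nm else paste(path, nm, sep = "$")
    if (!nm %in% names(defaults)) {
      abort(sprintf("unknown configuration key: `%s`", here))
    }
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]], here)
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' A single nested configuration document driving the whole chain
#' simulate -> preprocess -> decode -> temporal generalization -> RSA ->
#' fusion -> statistics. All stage seeds derive from the global `seed` plus
#' the stage name, so a configuration fully determines every output. The
#' `desk` preset (64 channels, 300 Hz, 10 subjects, 50 decoding iterations)
#' keeps a full run desk-sized; `paper` matches the full-scale recording
#' setup (272 channels, 1200 Hz, 17 subjects, 500 iterations). Unknown keys
#' are rejected before any computation. Round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Global integer seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @param overrides Named nested list of overrides, validated against the
#'   preset defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "paper"), seed = 1L,
                            out_dir = "repdyn-results", overrides = list()) {
  preset <- match.arg(preset)
  cfg <- default_pipeline_config(preset)
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON document.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(preset = raw$preset, seed = raw$seed,
                  out_dir = raw$out_dir,
                  overrides = raw[setdiff(names(raw),
                                          c("preset", "seed", "out_dir"))])
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> preset %s, seed %d, %d subjects, %d ch @ %g Hz\n",
    x$preset, x$seed, x$simulate$n_subjects, x$simulate$n_channels,
    x$simulate$sampling_rate))
  invisible(x)
}

log_stage <- function(state, stage, t0, detail = "") {
  line <- sprintf("[%s] %-22s %7.1fs %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0, detail)
  if (state$verbose) message(line)
  cat(line, "\n", file = state$log_path, append = TRUE)
}

write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> decode (task and object) -> temporal
#' generalization -> cross-task-type decoding -> RSA -> fusion -> cluster
#' statistics -> bootstrap latency CIs, writing every stage output (CSV +
#' JSON metadata, run log) into `config$out_dir` and returning a result
#' bundle of files with checksums. Re-running with the same configuration
#' reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return A `result_bundle`: tibble of files, stages and md5 checksums,
#'   with the in-memory stage results attached as attributes.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state <- list(verbose = isTRUE(config$io$verbose),
                log_path = file.path(out, "run_log.txt"))
  cat(sprintf("pipeline run, seed %d, preset %s\n", config$seed,
              config$preset),
      file = state$log_path)
  files <- list()
  add_file <- function(path, stage) {
    files[[length(files) + 1L]] <<- tibble(file = basename(path),
                                           stage = stage,
                                           md5 = unname(tools::md5sum(path)))
  }

  t0 <- as.numeric(Sys.time())
  write_pipeline_config(config, file.path(out, "config.json"))
  add_file(file.path(out, "config.json"), "config")

  ## --- simulate + preprocess + subject-level analyses -------------------
  spec <- do.call(design_spec, config$design)
  design <- generate_design(spec, seed = config$seed)
  add_file(write_stage_csv(design, file.path(out, "design.csv")), "simulate")
  truth <- do.call(ground_truth, config$truth)

  pp <- config$preprocess
  cfg_task <- preprocess_config(
    band = pp$band, notch = pp$notch,
    variance_drop_fraction = pp$variance_drop_fraction,
    max_drop_fraction = pp$max_drop_fraction,
    baseline_window = expected_baseline("task"),
    hdhm_ms = pp$hdhm_ms, target_rate = pp$target_rate)

  n_subj <- config$simulate$n_subjects
  run_subject <- function(s) {
    subject <- sprintf("s%02d", s)
    epochs <- generate_subject_epochs(
      design, truth, n_channels = config$simulate$n_channels,
      sampling_rate = config$simulate$sampling_rate,
      noise_sd = config$simulate$noise_sd,
      seed = derive_seed(config$seed, "subject", s), subject = subject)
    if (isTRUE(config$io$write_epochs)) {
      saveRDS(epochs, file.path(out, sprintf("epochs_%s.rds", subject)))
    }
    filtered <- filter_epochs(epochs, cfg_task)
    rm(epochs)
    fit <- fit_spatial_pca(filtered)
    rm(filtered)
    reduced <- drop_low_variance_components(fit$scores, fit$model,
                                            pp$variance_drop_fraction,
                                            pp$max_drop_fraction)
    fit$scores <- NULL
    # baseline normalization is per-component affine and commutes with the
    # unit-sum temporal smoothing, so smooth once and scale per branch
    stats_task <- baseline_stats(reduced, expected_baseline("task"))
    stats_obj <- baseline_stats(reduced, expected_baseline("category"))
    smoothed <- smooth_and_downsample(reduced, pp$hdhm_ms, pp$target_rate)
    task_data <- apply_baseline(smoothed, stats_task)
    object_data <- apply_baseline(smoothed, stats_obj)
    rm(fit, reduced, smoothed)
    gc(FALSE)

    dc <- config$decoding
    task <- decode_timecourse(
      task_data, decoding_config(dc$supertrial_size, dc$n_iterations, dc$C,
                                 "task",
                                 seed = derive_seed(config$seed, "dec", s)))
    object <- decode_timecourse(
      object_data, decoding_config(dc$supertrial_size, dc$n_iterations,
                                   dc$C, "category",
                                   seed = derive_seed(config$seed, "dec", s)))
    cross <- cross_tasktype_object_decode(
      object_data, decoding_config(dc$supertrial_size,
                                   config$cross$n_iterations,
                                   dc$C, "category",
                                   seed = derive_seed(config$seed, "x", s)))
    tempgen <- temporal_generalization(
      task_data, decoding_config(dc$supertrial_size,
                                 config$tempgen$n_iterations, dc$C, "task",
                                 seed = derive_seed(config$seed, "tg", s)),
      time_step = config$tempgen$time_step)
    list(task = task, object = object, within = cross$within,
         between = cross$between, tempgen = tempgen,
         rdm = rdm_timecourse(task_data))
  }

  # each subject runs in a forked child where fork is available, so the
  # large epoch intermediates are reclaimed by the OS between subjects
  use_fork <- .Platform$OS.type == "unix" &&
    requireNamespace("parallel", quietly = TRUE)
  subj_res <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    ts <- as.numeric(Sys.time())
    subj_res[[s]] <- if (use_fork) {
      job <- parallel::mcparallel(run_subject(s))
      got <- parallel::mccollect(job)[[1]]
      if (inherits(got, "try-error") || is.null(got)) {
        abort(sprintf("stage simulate/decode failed for subject %d: %s", s,
                      paste(as.character(got), collapse = " ")))
      }
      got
    } else {
      run_subject(s)
    }
    log_stage(state, sprintf("subject s%02d", s), ts)
  }
  task_curves <- lapply(subj_res, `[[`, "task")
  object_curves <- lapply(subj_res, `[[`, "object")
  within_curves <- lapply(subj_res, `[[`, "within")
  between_curves <- lapply(subj_res, `[[`, "between")
  tempgens <- lapply(subj_res, `[[`, "tempgen")
  rdm_list <- lapply(subj_res, `[[`, "rdm")
  rm(subj_res)

  curve_df <- function(curves) {
    dplyr::bind_rows(lapply(curves, tidy))
  }
  add_file(write_stage_csv(curve_df(task_curves),
                           file.path(out, "decoding_task.csv")), "decode")
  add_file(write_stage_csv(curve_df(object_curves),
                           file.path(out, "decoding_object.csv")), "decode")
  add_file(write_stage_csv(curve_df(within_curves),
                           file.path(out, "decoding_within_tasktype.csv")),
           "decode")
  add_file(write_stage_csv(curve_df(between_curves),
                           file.path(out, "decoding_between_tasktype.csv")),
           "decode")
  add_file(write_stage_csv(dplyr::bind_rows(lapply(tempgens, tidy)),
                           file.path(out, "tempgen_task.csv")), "tempgen")

  ## --- group statistics --------------------------------------------------
  ts <- as.numeric(Sys.time())
  st <- config$stats
  windowed <- function(curves, win) {
    m <- as_subject_matrix(curves)
    keep <- attr(m, "time") >= win[1] & attr(m, "time") <= win[2]
    structure(m[, keep, drop = FALSE], time = attr(m, "time")[keep])
  }
  cl_task <- sign_permutation_cluster_1d(
    windowed(task_curves, st$task_window), chance = 50, alpha = st$alpha,
    max_exhaustive = st$max_exhaustive, seed = derive_seed(config$seed, "c1"))
  cl_object <- sign_permutation_cluster_1d(
    windowed(object_curves, st$object_window), chance = 50,
    alpha = st$alpha, max_exhaustive = st$max_exhaustive,
    seed = derive_seed(config$seed, "c2"))
  add_file(write_stage_csv(tidy(cl_task),
                           file.path(out, "clusters_task.csv")), "stats")
  add_file(write_stage_csv(tidy(cl_object),
                           file.path(out, "clusters_object.csv")), "stats")

  tg_win <- lapply(tempgens, function(tg) {
    keep1 <- tg$train_time >= st$task_window[1] &
      tg$train_time <= st$task_window[2]
    tg$accuracy <- tg$accuracy[keep1, keep1, drop = FALSE]
    tg$train_time <- tg$train_time[keep1]
    tg$test_time <- tg$test_time[keep1]
    tg
  })
  cl_tg <- cluster_2d(tg_win, n_perm = min(st$n_perm_2d, 2^n_subj),
                      alpha = st$alpha,
                      seed = derive_seed(config$seed, "c3"))
  add_file(write_stage_csv(tidy(cl_tg),
                           file.path(out, "clusters_tempgen.csv")), "stats")
  log_stage(state, "cluster tests", ts)

  ## --- RSA + fusion -------------------------------------------------------
  ts <- as.numeric(Sys.time())
  group_rdms <- group_average_rdm(rdm_list)
  rdm_long <- tibble(
    time_ms = rep(group_rdms$time, times = ncol(group_rdms$rdv)),
    pair = rep(seq_len(ncol(group_rdms$rdv)), each = nrow(group_rdms$rdv)),
    dissimilarity = as.vector(group_rdms$rdv))
  add_file(write_stage_csv(rdm_long, file.path(out, "rdm_group.csv")), "rsa")

  fmri <- do.call(generate_fmri_patterns,
                  c(config$fmri, list(seed = derive_seed(config$seed,
                                                         "fmri"))))
  fmri_rdms <- roi_rdms(fmri)
  models <- list(task = model_rdm("task", group_rdms$condition_order),
                 category = model_rdm("category", group_rdms$condition_order))
  fusion <- run_fusion(group_rdms, fmri_rdms, models)
  add_file(write_stage_csv(as_tibble(fusion),
                           file.path(out, "fusion.csv")), "fusion")

  cl_fusion <- rdm_randomization_cluster(
    group_rdms, fmri_rdms, models, n_perm = st$n_perm_fusion,
    alpha = st$alpha, seed = derive_seed(config$seed, "c4"),
    statistics = c("c_task", "c_category"))
  add_file(write_stage_csv(tidy(cl_fusion),
                           file.path(out, "clusters_fusion.csv")), "stats")
  log_stage(state, "rsa + fusion", ts)

  ## --- bootstrap latency CIs ---------------------------------------------
  ts <- as.numeric(Sys.time())
  ci_task <- bootstrap_peak_ci(task_curves, st$task_peak_window,
                               n_boot = st$n_boot_decoding,
                               seed = derive_seed(config$seed, "b1"))
  ci_object <- bootstrap_peak_ci(object_curves, st$object_peak_window,
                                 n_boot = st$n_boot_decoding,
                                 seed = derive_seed(config$seed, "b2"))
  ci_fusion <- bootstrap_peak_ci_fusion(
    rdm_list, fmri_rdms[[1]], models, statistic = "c_category",
    window_ms = st$object_peak_window, n_boot = st$n_boot_fusion,
    seed = derive_seed(config$seed, "b3"))
  cis <- dplyr::bind_rows(
    dplyr::mutate(tidy(ci_task), which = "task_peak", .before = 1L),
    dplyr::mutate(tidy(ci_object), which = "object_peak", .before = 1L),
    dplyr::mutate(tidy(ci_fusion), which = "fusion_c_category_peak",
                  .before = 1L))
  add_file(write_stage_csv(cis, file.path(out, "peak_cis.csv")), "stats")
  log_stage(state, "bootstrap CIs", ts)

  bundle <- dplyr::bind_rows(files)
  provenance <- list(
    c("simulate", "decode"), c("simulate", "tempgen"), c("simulate", "rsa"),
    c("decode", "stats"), c("tempgen", "stats"), c("rsa", "fusion"),
    c("fusion", "stats"))
  jsonlite::write_json(
    list(files = bundle, provenance = provenance, seed = config$seed),
    file.path(out, "bundle.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  log_stage(state, "total", t0)

  structure(bundle,
            class = c("result_bundle", class(bundle)),
            out_dir = out, config = config, provenance = provenance,
            results = list(
              task_curves = task_curves, object_curves = object_curves,
              within_curves = within_curves, between_curves = between_curves,
              tempgen = tempgens, rdm_group = group_rdms, fusion = fusion,
              clusters = list(task = cl_task, object = cl_object,
                              tempgen = cl_tg, fusion = cl_fusion),
              peak_cis = list(task = ci_task, object = ci_object,
                              fusion = ci_fusion)))
}

#' Read a result bundle back from disk
#'
#' Verifies the checksum of every file recorded in `bundle.json` and loads
#' the tabular outputs. A checksum mismatch (e.g. a truncated file) is an
#' error.
#'
#' @param dir Directory written by [run_pipeline()].
#' @return List with the bundle table and the loaded stage tables.
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  bundle <- as_tibble(meta$files)
  for (i in seq_len(nrow(bundle))) {
    path <- file.path(dir, bundle$file[i])
    if (!file.exists(path)) abort(sprintf("missing bundle file: %s", path))
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, bundle$md5[i])) {
      abort(sprintf("checksum mismatch for %s", bundle$file[i]))
    }
  }
  tables <- list()
  for (f in bundle$file[grepl("\\.csv$", bundle$file)]) {
    tables[[sub("\\.csv$", "", f)]] <- as_tibble(
      read.csv(file.path(dir, f)))
  }
  list(bundle = bundle, tables = tables,
       config = read_pipeline_config(file.path(dir, "config.json")))
}
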
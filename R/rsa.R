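#' Canonical task-major condition ordering
#'
#' Conditions are ordered task-major: all categories of task 1, then of
#' task 2, and so on. Every RDM-level artifact carries this ordering and all
#' cross-modal operations verify ordering equality rather than assuming it.
#'
#' @param tasks,categories Level vectors.
#' @return Tibble with columns `task`, `category` (one row per condition).
#' @export
condition_order <- function(tasks = task_levels(4),
                            categories = category_levels(8)) {
  tidyr::expand_grid(task = tasks, category = categories)
}

condition_labels <- function(order) {
  if (all(is.na(order$task))) return(as.character(order$category))
  paste(order$task, order$category, sep = ".")
}

same_order <- function(a, b) {
  identical(condition_labels(a), condition_labels(b))
}

#' Mean activity pattern per task x category condition
#'
#' Averages trials within each (task, category) cell at every time point,
#' excluding catch trials. The canonical design yields 32 condition patterns
#' (4 tasks x 8 categories).
#'
#' @param dataset Component `epochs`.
#' @return A `condition_patterns` object: array (condition x component x
#'   time) with `condition_order` and time axis.
#' @export
condition_mean_patterns <- function(dataset) {
  stopifnot(inherits(dataset, "epochs"))
  dataset <- epochs_experimental(dataset)
  tasks <- sort(unique(dataset$trials$task))
  if (setequal(tasks, task_levels(4))) tasks <- task_levels(4)
  cats <- sort(unique(dataset$trials$category))
  order <- condition_order(tasks, cats)

  cell <- match(
    paste(dataset$trials$task, dataset$trials$category, sep = "."),
    condition_labels(order))
  counts <- tabulate(cell, nbins = nrow(order))
  if (any(counts == 0L)) {
    abort(sprintf("no trials for condition(s): %s",
                  paste(condition_labels(order)[counts == 0L],
                        collapse = ", ")))
  }

  d <- dim(dataset$data)
  flat <- dataset$data
  dim(flat) <- c(d[1], d[2] * d[3])
  sums <- rowsum(flat, cell)
  means <- sums[order(as.integer(rownames(sums))), , drop = FALSE] / counts
  dim(means) <- c(nrow(order), d[2], d[3])

  structure(
    list(patterns = means, condition_order = order, time = dataset$time,
         subject = dataset$subject),
    class = "condition_patterns")
}

new_rdm <- function(mat, order, time_ms = NULL, roi = NULL) {
  dimnames(mat) <- list(condition_labels(order), condition_labels(order))
  structure(
    list(matrix = mat, condition_order = order, time_ms = time_ms,
         roi = roi),
    class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d (1 - Pearson r)%s%s\n", nrow(x$matrix),
              ncol(x$matrix),
              if (!is.null(x$time_ms)) sprintf(", t = %g ms", x$time_ms)
              else "",
              if (!is.null(x$roi)) sprintf(", ROI %s", x$roi) else ""))
  invisible(x)
}

#' Correlation-distance representational dissimilarity matrix
#'
#' Entry (i, j) is 1 minus the Pearson correlation between condition patterns
#' i and j: 0 for identical (up to affine rescaling), 1 for uncorrelated, 2
#' for anti-correlated patterns. Symmetric with a zero diagonal.
#'
#' @param patterns Condition x unit matrix (one pattern per row), or a
#'   `condition_patterns` object plus `time_index`.
#' @param order Condition ordering tibble; defaults to row order.
#' @param time_ms,roi Optional stamps recorded on the result.
#' @return An `rdm` object.
#' @export
compute_rdm <- function(patterns, order = NULL, time_ms = NULL, roi = NULL) {
  if (inherits(patterns, "condition_patterns")) {
    abort("use `rdm_timecourse()` for condition_patterns input")
  }
  stopifnot(is.matrix(patterns))
  if (any(apply(patterns, 1L, var) <= 0)) {
    abort("every pattern must have nonzero variance")
  }
  if (is.null(order)) {
    order <- tibble(task = NA_character_,
                    category = rownames(patterns) %||%
                      sprintf("p%d", seq_len(nrow(patterns))))
  }
  m <- 1 - cor(t(patterns))
  diag(m) <- 0
  new_rdm(m, order, time_ms = time_ms, roi = roi)
}

#' Binary model RDM for a factor
#'
#' Expected dissimilarity under a pure factor representation: 0 where two
#' conditions share the factor level, 1 where they differ. In the canonical
#' 32-condition ordering the task model's lower triangle holds 112 zeros
#' (4 * choose(8, 2)) and the category model's 48 (8 * choose(4, 2)).
#'
#' @param factor `"task"` or `"category"`.
#' @param order Condition ordering tibble (see [condition_order()]).
#' @return An `rdm` with binary entries.
#' @export
model_rdm <- function(factor = c("task", "category"),
                      order = condition_order()) {
  factor <- match.arg(factor)
  lev <- order[[factor]]
  m <- 1 - outer(lev, lev, "==")
  storage.mode(m) <- "double"
  new_rdm(m, order, roi = NULL)
}

#' Vectorize an RDM (lower triangle, excluding the diagonal)
#'
#' Column-major scan of the strictly lower triangle; a 32 x 32 RDM gives a
#' length-496 representational dissimilarity vector (RDV).
#'
#' @param rdm An `rdm` object or symmetric matrix.
#' @param tol Maximum allowed asymmetry.
#' @return Numeric RDV with the condition ordering attached as an attribute.
#' @export
rdv <- function(rdm, tol = 1e-8) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else rdm
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) abort("RDM is asymmetric beyond tolerance")
  v <- m[lower.tri(m)]
  attr(v, "condition_order") <- if (inherits(rdm, "rdm")) rdm$condition_order
  v
}

#' Rebuild a symmetric zero-diagonal matrix from an RDV
#'
#' Inverse of [rdv()].
#'
#' @param v RDV as returned by [rdv()].
#' @param order Optional condition ordering.
#' @return An `rdm` object.
#' @export
rdv_to_rdm <- function(v, order = attr(v, "condition_order")) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) abort("RDV length is not n(n-1)/2 for integer n")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (is.null(order)) {
    order <- tibble(task = NA_character_, category = sprintf("p%d", 1:n))
  }
  new_rdm(m, order)
}

#' Time-resolved RDM series from condition patterns
#'
#' Computes the 1 - Pearson RDM at every time point and stores the series as
#' a time x RDV matrix.
#'
#' @param x `condition_patterns` (from [condition_mean_patterns()]) or a
#'   component `epochs` object.
#' @return An `rdm_series`: fields `rdv` (time x n_pairs matrix), `time`,
#'   `condition_order`.
#' @export
rdm_timecourse <- function(x) {
  if (inherits(x, "epochs")) x <- condition_mean_patterns(x)
  stopifnot(inherits(x, "condition_patterns"))
  d <- dim(x$patterns)
  n_pair <- d[1] * (d[1] - 1) / 2
  lower <- lower.tri(matrix(0, d[1], d[1]))
  out <- matrix(NA_real_, d[3], n_pair)
  for (t in seq_len(d[3])) {
    m <- 1 - cor(t(x$patterns[, , t]))
    out[t, ] <- m[lower]
  }
  structure(
    list(rdv = out, time = x$time, condition_order = x$condition_order,
         subject = x$subject),
    class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> %d time points x %d condition pairs\n",
              nrow(x$rdv), ncol(x$rdv)))
  invisible(x)
}

#' Entrywise average of RDMs or RDM series
#'
#' Inputs must share the same condition ordering; ordering mismatches are an
#' error, never silently reconciled. Used to form the group-average RDMs that
#' enter fusion.
#'
#' @param rdms List of `rdm` objects, or list of `rdm_series`.
#' @return An object of the same class as the inputs.
#' @export
group_average_rdm <- function(rdms) {
  stopifnot(length(rdms) >= 1L)
  if (inherits(rdms[[1]], "rdm_series")) {
    for (r in rdms) {
      if (!same_order(r$condition_order, rdms[[1]]$condition_order)) {
        abort("condition ordering differs between RDM series")
      }
    }
    out <- rdms[[1]]
    out$rdv <- Reduce(`+`, lapply(rdms, `[[`, "rdv")) / length(rdms)
    out$subject <- "group"
    return(out)
  }
  stopifnot(inherits(rdms[[1]], "rdm"))
  for (r in rdms) {
    if (!same_order(r$condition_order, rdms[[1]]$condition_order)) {
      abort("condition ordering differs between RDMs")
    }
  }
  out <- rdms[[1]]
  out$matrix <- Reduce(`+`, lapply(rdms, `[[`, "matrix")) / length(rdms)
  out
}

#' Write / read an RDM as labelled CSV
#'
#' The matrix is written with header-labelled columns and a leading
#' `condition` column holding the row labels (task.category), so the
#' condition ordering travels with the file and round-trips losslessly.
#'
#' @param rdm An `rdm` object.
#' @param path CSV file path.
#' @return `write_rdm` the path, invisibly; `read_rdm` an `rdm` object.
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  df <- data.frame(condition = rownames(rdm$matrix), rdm$matrix,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$condition
  labels <- strsplit(df$condition, ".", fixed = TRUE)
  order <- tibble(task = vapply(labels, `[`, "", 1L),
                  category = vapply(labels, function(x) {
                    paste(x[-1], collapse = ".")
                  }, ""))
  new_rdm(m, order)
}

#' RDMs of a synthetic ROI pattern set
#'
#' @param pattern_set A [generate_fmri_patterns()] result.
#' @return Named list of `rdm` objects, one per ROI.
#' @export
roi_rdms <- function(pattern_set) {
  stopifnot(inherits(pattern_set, "roi_pattern_set"))
  lapply(setNames(names(pattern_set$patterns), names(pattern_set$patterns)),
         function(nm) {
           compute_rdm(pattern_set$patterns[[nm]],
                       order = pattern_set$condition_order, roi = nm)
         })
}
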
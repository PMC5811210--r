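#' Squared Spearman correlation between two RDVs
#'
#' Square of the rank correlation (average ranks for ties), equivalently the
#' coefficient of determination of one rank-transformed RDV explaining the
#' other. Always in \[0, 1\].
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return Scalar in \[0, 1\].
#' @export
spearman_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector in spearman_r2")
  cor(rank(x), rank(y))^2
}

#' Squared semi-partial Spearman correlation
#'
#' All vectors are rank-transformed (average ties); the ranks of `y` are
#' residualized on the ranks of the `partial_set` vectors (plus an intercept)
#' by least squares, and the squared Pearson correlation between the ranks of
#' `x` and that residual is returned. With an empty `partial_set` this equals
#' [spearman_r2()]. If the partial set explains `y`'s ranks completely the
#' result is defined as 0, with a warning.
#'
#' @param x,y Equal-length numeric vectors.
#' @param partial_set List of equal-length, non-constant numeric vectors to
#'   partial out of `y`.
#' @return Scalar in \[0, 1\].
#' @export
semipartial_spearman_r2 <- function(x, y, partial_set = list()) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(partial_set) == 0L) return(spearman_r2(x, y))
  for (p in partial_set) {
    stopifnot(length(p) == length(y))
    if (sd(p) == 0) abort("constant vector in partial_set")
  }
  ry <- rank(y)
  z <- cbind(1, do.call(cbind, lapply(partial_set, rank)))
  res <- lm.fit(z, ry)$residuals
  if (var(res) < 1e-12 * var(ry)) {
    warn("residual of y on the partial set has ~zero variance; returning 0")
    return(0)
  }
  cor(rank(x), res)^2
}

#' Commonality of two model RDVs in explaining shared x-y variance
#'
#' Variance partitioning of the squared Spearman correlation between `x`
#' (e.g. the MEG RDV at one time point) and `y` (e.g. an ROI's fMRI RDV):
#' the commonality of model `a` is the part of the x-y shared variance
#' uniquely attributable to `a`,
#' `C_a = R2(x, y.b) - R2(x, y.ab)` (squared semi-partial Spearman
#' correlations), and symmetrically for `b`. Commonalities can slightly
#' exceed the total R2 or dip slightly negative (suppression, numerical
#' error); they are deliberately not clipped.
#'
#' @param x,y Target RDVs.
#' @param a,b Model RDVs (e.g. binary task and category models), non-constant.
#' @return Named list: `c_a`, `c_b`, `r2_total`.
#' @export
commonality <- function(x, y, a, b) {
  list(
    c_a = semipartial_spearman_r2(x, y, list(b)) -
      semipartial_spearman_r2(x, y, list(a, b)),
    c_b = semipartial_spearman_r2(x, y, list(a)) -
      semipartial_spearman_r2(x, y, list(a, b)),
    r2_total = spearman_r2(x, y))
}

# --- fast fusion engine -----------------------------------------------------
# center-and-scale so that cor(u, v) = sum(zu * zv) / (n - 1)
zscale <- function(v) {
  s <- sd(v)
  if (s == 0) return(NULL)
  (v - mean(v)) / s
}

# Per-ROI precomputation: scaled ranks of y and scaled residuals of y-ranks
# on the model ranks. The MEG side only ever enters through dot products with
# these fixed vectors, which is what makes randomization and bootstrap loops
# cheap.
fusion_precompute <- function(fmri_rdvs, a_rdv, b_rdv) {
  ra <- rank(a_rdv)
  rb <- rank(b_rdv)
  lapply(fmri_rdvs, function(y) {
    ry <- rank(y)
    res_b <- lm.fit(cbind(1, rb), ry)$residuals
    res_a <- lm.fit(cbind(1, ra), ry)$residuals
    res_ab <- lm.fit(cbind(1, ra, rb), ry)$residuals
    cols <- lapply(list(y = ry, yb = res_b, ya = res_a, yab = res_ab), zscale)
    if (any(vapply(cols, is.null, TRUE))) {
      warn("an fMRI RDV is fully explained by the models; commonalities set to 0 where undefined")
      cols <- lapply(cols, function(v) v %||% rep(0, length(ry)))
    }
    do.call(cbind, cols)
  })
}

# meg_rank_z: time x n_pairs matrix of scaled MEG RDV ranks
fusion_curves_from_ranks <- function(meg_rank_z, precomp) {
  n <- ncol(meg_rank_z)
  lapply(precomp, function(u) {
    r <- (meg_rank_z %*% u / (n - 1))^2   # squared correlations
    tibble(r2_total = r[, "y"],
           c_task = r[, "yb"] - r[, "yab"],
           c_category = r[, "ya"] - r[, "yab"])
  })
}

rank_z_rows <- function(m) {
  t(apply(m, 1L, function(v) {
    z <- zscale(rank(v))
    if (is.null(z)) rep(0, length(v)) else z
  }))
}

#' Model-based MEG-fMRI fusion with commonality analysis
#'
#' For every ROI and MEG time point, computes the total shared variance
#' (squared Spearman correlation between the MEG RDV and the ROI's fMRI RDV)
#' and the commonality coefficients for the task and category models via
#' [commonality()]. All inputs must share the same condition ordering.
#' Intended for group-average RDMs.
#'
#' @param meg_rdms An `rdm_series` (typically the group average).
#' @param fmri_rdms Named list of per-ROI `rdm` objects.
#' @param models List with elements `task` and `category` ([model_rdm()]s).
#' @param target Which modality the models are partialled from: `"meg"`
#'   (default; models are partialled out of the fMRI RDV) or `"fmri"`
#'   (roles swapped). The result pattern is typically comparable but not
#'   identical between targets.
#' @return A `fusion_result`: long tibble (roi, time_ms, r2_total, c_task,
#'   c_category) with metadata attributes.
#' @export
run_fusion <- function(meg_rdms, fmri_rdms, models =
                         list(task = model_rdm("task"),
                              category = model_rdm("category")),
                       target = c("meg", "fmri")) {
  target <- match.arg(target)
  stopifnot(inherits(meg_rdms, "rdm_series"))
  ord <- meg_rdms$condition_order
  for (r in fmri_rdms) {
    if (!same_order(r$condition_order, ord)) {
      abort("fMRI RDM condition ordering does not match the MEG series")
    }
  }
  for (m in models) {
    if (!same_order(m$condition_order, ord)) {
      abort("model RDM condition ordering does not match the MEG series")
    }
  }
  a <- rdv(models$task)
  b <- rdv(models$category)
  fmri_rdvs <- lapply(fmri_rdms, rdv)

  if (target == "meg") {
    precomp <- fusion_precompute(fmri_rdvs, a, b)
    zx <- rank_z_rows(meg_rdms$rdv)
    curves <- fusion_curves_from_ranks(zx, precomp)
  } else {
    # partial the models out of the MEG RDV at each time point
    ra <- rank(a)
    rb <- rank(b)
    curves <- lapply(fmri_rdvs, function(y) {
      zy <- zscale(rank(y))
      out <- matrix(NA_real_, nrow(meg_rdms$rdv), 3L)
      for (t in seq_len(nrow(meg_rdms$rdv))) {
        rx <- rank(meg_rdms$rdv[t, ])
        zb <- zscale(lm.fit(cbind(1, rb), rx)$residuals)
        za <- zscale(lm.fit(cbind(1, ra), rx)$residuals)
        zab <- zscale(lm.fit(cbind(1, ra, rb), rx)$residuals)
        n <- length(rx)
        r2 <- function(z) {
          if (is.null(z)) 0 else (sum(zy * z) / (n - 1))^2
        }
        out[t, ] <- c((sum(zy * zscale(rx)) / (n - 1))^2,
                      r2(zb) - r2(zab), r2(za) - r2(zab))
      }
      tibble(r2_total = out[, 1], c_task = out[, 2], c_category = out[, 3])
    })
  }

  res <- dplyr::bind_rows(
    lapply(names(curves), function(nm) {
      dplyr::mutate(curves[[nm]], roi = nm, time_ms = meg_rdms$time,
                    .before = 1L)
    }))
  structure(res,
            class = c("fusion_result", class(res)),
            target = target,
            condition_order = ord,
            rois = names(curves),
            time = meg_rdms$time)
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d ROIs x %d time points (target: %s)\n",
              length(attr(x, "rois")), length(attr(x, "time")),
              attr(x, "target")))
  NextMethod()
}
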
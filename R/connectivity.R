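# Informational connectivity: covariation of trial-wise AMI series across
# ROIs, plus the mean-BOLD control connectivity.

#' Cross-validated trial-wise AMI within the attention task
#'
#' Leave-one-run-out scheme: for each attention trial of a held-out run, the
#' Mahalanobis distances to the two attended-orientation distributions are
#' estimated from the remaining runs (reference means per orientation,
#' covariance pooled over both conditions), and the AMI is formed with the
#' trial's own label defining the "same" condition.  The series is returned
#' in acquisition order (run, then trial index).
#'
#' @param ps Attention-task [pattern_set()] (filtered, z-normalized) whose
#'   meta has `run` and `orientation`.
#' @param shrinkage Covariance regularization intensity.
#' @return An `ami_series` with `scheme = "attention_crossval"`.
#' @export
trialwise_ami_crossval <- function(ps, shrinkage = 0.1) {
  stopifnot(inherits(ps, "pattern_set"))
  runs <- ps$meta$run
  if (length(unique(runs)) < 2L) stop("need >= 2 runs", call. = FALSE)
  ori <- as.character(ps$meta$orientation)
  orientations <- c("leftward", "rightward")
  values <- numeric(nrow(ps$matrix))
  for (r in sort(unique(runs))) {
    test <- which(runs == r)
    train <- which(runs != r)
    refs <- lapply(orientations, function(o) {
      ps$matrix[train[ori[train] == o], , drop = FALSE]
    })
    names(refs) <- orientations
    if (any(vapply(refs, nrow, 1L) < 2L)) {
      stop("training fold (held-out run ", r,
           ") is missing an attention condition", call. = FALSE)
    }
    ch <- pooled_ref_cov(refs, shrinkage)
    d_to <- vapply(orientations, function(o) {
      mahal_rows(ps$matrix[test, , drop = FALSE], colMeans(refs[[o]]), ch)
    }, numeric(length(test)))
    same <- ifelse(ori[test] == "leftward", d_to[, "leftward"],
                   d_to[, "rightward"])
    diff <- ifelse(ori[test] == "leftward", d_to[, "rightward"],
                   d_to[, "leftward"])
    values[test] <- ami(same, diff)
  }
  ord <- order(ps$meta$run, ps$meta$trial_index_in_run)
  new_ami_series(values[ord], ps$meta[ord, , drop = FALSE], ps$roi,
                 "attention_crossval")
}

new_ic_matrix <- function(r_mat, n, kind) {
  z <- fisher_z(r_mat)
  diag(z) <- NA_real_
  diag(r_mat) <- NA_real_
  structure(list(r = r_mat, z = z, n = n, kind = kind), class = "ic_matrix")
}

#' @export
print.ic_matrix <- function(x, ...) {
  cat("Connectivity matrix (", x$kind, "), n = ", x$n, "\n", sep = "")
  print(round(x$z, 3))
  invisible(x)
}

#' Informational connectivity between ROIs
#'
#' Pairwise Pearson correlation of aligned trial-wise AMI series, Fisher
#' z-transformed (with `|r|` clipped to `1 - 1e-6` before `atanh`).  Series
#' are aligned by trial identifiers (run, trial index), not position, so a
#' trial filtered out in one ROI must be absent everywhere.
#'
#' @param series_by_roi Named list of `ami_series`, one per ROI.
#' @return An `ic_matrix`: ROI x ROI matrices `r` and `z` (diagonal masked),
#'   with `n` the number of aligned trials.
#' @export
informational_connectivity <- function(series_by_roi) {
  stopifnot(is.list(series_by_roi), length(series_by_roi) >= 2L)
  if (is.null(names(series_by_roi))) {
    names(series_by_roi) <- vapply(series_by_roi, `[[`, "", "roi")
  }
  key <- function(s) paste(s$series$run, s$series$trial_index_in_run)
  k0 <- key(series_by_roi[[1]])
  for (s in series_by_roi[-1]) {
    if (!identical(key(s), k0)) {
      stop("AMI series are not aligned on the same trials", call. = FALSE)
    }
  }
  mat <- vapply(series_by_roi, function(s) s$series$ami,
                numeric(length(k0)))
  if (any(apply(mat, 2L, stats::sd) == 0)) {
    stop("zero-variance AMI series", call. = FALSE)
  }
  new_ic_matrix(stats::cor(mat), nrow(mat), "informational")
}

#' Mean-BOLD control connectivity
#'
#' The univariate control for informational connectivity: each ROI is
#' reduced to its spatial-mean response series (per run, concatenated in
#' run order when runs are supplied separately), and ROI pairs are
#' correlated and Fisher z-transformed.  An informational-connectivity
#' effect that is absent here cannot be carried by overall response
#' amplitude.
#'
#' @param ts_by_roi Named list, one element per ROI: a numeric matrix
#'   (time or trials x voxels), a list of such per-run matrices, or an
#'   already-averaged numeric vector.
#' @return An `ic_matrix` with `kind = "mean_bold"`.
#' @export
mean_bold_connectivity <- function(ts_by_roi) {
  stopifnot(is.list(ts_by_roi), length(ts_by_roi) >= 2L)
  roi_mean <- function(x) {
    if (is.list(x)) unlist(lapply(x, roi_mean), use.names = FALSE)
    else if (is.matrix(x)) rowMeans(x)
    else as.numeric(x)
  }
  series <- lapply(ts_by_roi, roi_mean)
  n <- unique(vapply(series, length, 1L))
  if (length(n) != 1L) {
    stop("ROI mean series have different lengths", call. = FALSE)
  }
  mat <- do.call(cbind, series)
  if (any(apply(mat, 2L, stats::sd) == 0)) {
    stop("zero-variance ROI mean series", call. = FALSE)
  }
  new_ic_matrix(stats::cor(mat), n, "mean_bold")
}
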
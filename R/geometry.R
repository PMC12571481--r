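# Mahalanobis-distance representational geometry and the attentional
# modulation index (AMI).

# Pooled reference covariance: mean-center each reference condition, pool
# the centered rows, shrink toward the scaled identity.  Returns the
# Cholesky factor so many distances share one factorization.
pooled_ref_cov <- function(ref_list, shrinkage) {
  v <- ncol(ref_list[[1]])
  centered <- lapply(ref_list, function(m) sweep(m, 2L, colMeans(m)))
  xc <- do.call(rbind, centered)
  n_eff <- nrow(xc) - length(ref_list)
  if (n_eff < 1L) stop("reference sets too small to estimate covariance",
                       call. = FALSE)
  s <- crossprod(xc) / n_eff
  sig <- (1 - shrinkage) * s
  diag(sig) <- diag(sig) + shrinkage * sum(diag(s)) / v
  ch <- tryCatch(chol(sig), error = function(e) {
    stop("reference covariance is singular with shrinkage = 0; ",
         "use shrinkage > 0", call. = FALSE)
  })
  ch
}

# sqrt((x - mu)' Sigma^-1 (x - mu)) for each row of x, given chol(Sigma).
mahal_rows <- function(x, mu, chol_sigma) {
  d <- sweep(x, 2L, mu)
  z <- backsolve(chol_sigma, t(d), transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Mahalanobis distance from a pattern to a reference distribution
#'
#' `d = sqrt((x - mu)' Sigma^-1 (x - mu))` where `mu` is the reference mean
#' and `Sigma` the shrinkage-regularized covariance of the reference trials
#' (`(1-alpha) S + alpha (tr S / V) I`).
#'
#' @param x Pattern vector (or matrix of patterns, one per row).
#' @param ref Reference trial matrix (>= 2 rows), or a list of reference
#'   matrices whose covariance is pooled after within-condition centering
#'   (the mean is then taken from the first element).
#' @param shrinkage Regularization intensity; with 0 a singular covariance
#'   raises an error recommending shrinkage.
#' @return Distance(s), one per row of `x`.
#' @export
#' @examples
#' ref <- matrix(rnorm(200), 100, 2)
#' mahalanobis_to_distribution(c(3, 4), ref)
mahalanobis_to_distribution <- function(x, ref, shrinkage = 0.1) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ref_list <- if (is.list(ref)) ref else list(ref)
  if (any(vapply(ref_list, nrow, 1L) < 2L)) {
    stop("each reference set needs >= 2 trials", call. = FALSE)
  }
  if (ncol(x) != ncol(ref_list[[1]])) {
    stop("dimension mismatch between pattern and reference", call. = FALSE)
  }
  ch <- pooled_ref_cov(ref_list, shrinkage)
  mahal_rows(x, colMeans(ref_list[[1]]), ch)
}

#' Attentional modulation index
#'
#' `AMI = (D_different - D_same) / (D_different + D_same)`: positive when a
#' pattern is closer to its matching condition, negative when closer to the
#' opposite condition.  Vectorized; antisymmetric under swapping the two
#' distances.
#'
#' @param d_same,d_different Non-negative distances.
#' @return AMI value(s) in `[-1, 1]`.
#' @export
#' @examples
#' ami(1, 3)  # 0.5
ami <- function(d_same, d_different) {
  stopifnot(is.numeric(d_same), is.numeric(d_different))
  if (any(d_same < 0) || any(d_different < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  tot <- d_same + d_different
  if (any(tot == 0)) {
    stop("AMI undefined: both distances are zero", call. = FALSE)
  }
  (d_different - d_same) / tot
}

#' Attention-to-perception Mahalanobis distance table
#'
#' For every attention trial, computes the Mahalanobis distance to each of
#' the two perceived-orientation distributions (reference mean per
#' orientation, covariance pooled over both perception conditions after
#' within-condition centering, shared across cells).  Cell values are means
#' over the trials of each attention condition; `D_same` averages the
#' matched pairs, `D_different` the mismatched pairs.
#'
#' @param prep Attention-task [pattern_set()] (typically preparation or
#'   selection period, filtered and z-normalized).
#' @param perc Perception-task [pattern_set()] (filtered and z-normalized).
#' @param shrinkage Covariance regularization intensity.
#' @return An object of class `distance_table`: the 2 x 2 `cells` matrix
#'   (rows = attended, columns = perceived orientation), `d_same`,
#'   `d_different`, `ami`, identifiers, and trial counts.
#' @export
distance_table <- function(prep, perc, shrinkage = 0.1) {
  stopifnot(inherits(prep, "pattern_set"), inherits(perc, "pattern_set"))
  orientations <- c("leftward", "rightward")
  refs <- lapply(orientations, function(o) {
    perc$matrix[perc$meta$orientation == o, , drop = FALSE]
  })
  names(refs) <- orientations
  if (any(vapply(refs, nrow, 1L) < 2L)) {
    stop("each perceived orientation needs >= 2 reference trials",
         call. = FALSE)
  }
  ch <- pooled_ref_cov(refs, shrinkage)
  att_ori <- as.character(prep$meta$orientation)
  if (!all(orientations %in% att_ori)) {
    stop("both attended orientations must be present", call. = FALSE)
  }
  d_to <- vapply(orientations, function(o) {
    mahal_rows(prep$matrix, colMeans(refs[[o]]), ch)
  }, numeric(nrow(prep$matrix)))
  cells <- matrix(NA_real_, 2, 2, dimnames = list(
    attended = orientations, perceived = orientations))
  for (a in orientations) {
    for (p in orientations) {
      cells[a, p] <- mean(d_to[att_ori == a, p])
    }
  }
  d_same <- mean(c(cells["leftward", "leftward"],
                   cells["rightward", "rightward"]))
  d_diff <- mean(c(cells["leftward", "rightward"],
                   cells["rightward", "leftward"]))
  structure(
    list(roi = prep$roi, cells = cells, d_same = d_same,
         d_different = d_diff, ami = ami(d_same, d_diff),
         n_attention = nrow(prep$matrix), n_perception = nrow(perc$matrix),
         subject = if ("subject" %in% names(prep$meta))
           prep$meta$subject[1] else NA_character_,
         session = if ("session" %in% names(prep$meta))
           prep$meta$session[1] else NA_character_,
         period = if ("period" %in% names(prep$meta))
           prep$meta$period[1] else NA_character_),
    class = "distance_table"
  )
}

#' @export
print.distance_table <- function(x, ...) {
  cat("Distance table [", x$roi, "] D_same =", sprintf("%.3f", x$d_same),
      " D_different =", sprintf("%.3f", x$d_different),
      " AMI =", sprintf("%.4f", x$ami), "\n")
  invisible(x)
}

new_ami_series <- function(values, meta, roi, scheme) {
  stopifnot(length(values) == nrow(meta))
  if (any(!is.finite(values))) stop("non-finite AMI values", call. = FALSE)
  structure(
    list(roi = roi, scheme = scheme,
         series = data.frame(run = meta$run,
                             trial_index_in_run = meta$trial_index_in_run,
                             orientation = meta$orientation,
                             ami = values)),
    class = "ami_series"
  )
}

#' @export
print.ami_series <- function(x, ...) {
  cat("AMI series [", x$roi, ", ", x$scheme, "]: ", nrow(x$series),
      " trials, mean ", sprintf("%.4f", mean(x$series$ami)), "\n", sep = "")
  invisible(x)
}

#' Trial-wise AMI against perception references
#'
#' For each attention trial, computes the Mahalanobis distance to the
#' same-orientation and different-orientation perception distributions (the
#' trial's own attended orientation defines "same") and forms the AMI.
#'
#' @param ps Attention-task [pattern_set()].
#' @param perc Perception-task [pattern_set()].
#' @param shrinkage Covariance regularization intensity.
#' @return An object of class `ami_series` (`scheme = "perception_ref"`);
#'   `$series` is ordered as the input trials (acquisition order).
#' @export
trialwise_ami <- function(ps, perc, shrinkage = 0.1) {
  stopifnot(inherits(ps, "pattern_set"), inherits(perc, "pattern_set"))
  orientations <- c("leftward", "rightward")
  refs <- lapply(orientations, function(o) {
    perc$matrix[perc$meta$orientation == o, , drop = FALSE]
  })
  names(refs) <- orientations
  ch <- pooled_ref_cov(refs, shrinkage)
  d_to <- vapply(orientations, function(o) {
    mahal_rows(ps$matrix, colMeans(refs[[o]]), ch)
  }, numeric(nrow(ps$matrix)))
  ori <- as.character(ps$meta$orientation)
  same <- ifelse(ori == "leftward", d_to[, "leftward"], d_to[, "rightward"])
  diff <- ifelse(ori == "leftward", d_to[, "rightward"], d_to[, "leftward"])
  new_ami_series(ami(same, diff), ps$meta, ps$roi, "perception_ref")
}

#' Sort trials into strong and weak modulation groups
#'
#' Sorts single-trial AMI values in descending order; the top `floor(q * N)`
#' trials form the strong-modulation group and the bottom `floor(q * N)` the
#' weak-modulation group, with behavioral summaries for each.
#'
#' @param series An `ami_series` (e.g., [trialwise_ami()]).
#' @param behavior Data frame aligned with `series$series` (same trial
#'   order) containing `rt` and `correct`.
#' @param q Quantile fraction in `(0, 0.5]`.
#' @return A list with `strong` and `weak` (each: trial indices into the
#'   series, `mean_rt`, `accuracy`), plus `n_per_group`.
#' @export
sort_trials_by_ami <- function(series, behavior, q = 0.25) {
  stopifnot(inherits(series, "ami_series"), is.data.frame(behavior))
  if (q <= 0 || q > 0.5) stop("`q` must lie in (0, 0.5]", call. = FALSE)
  n <- nrow(series$series)
  if (nrow(behavior) != n) {
    stop("behavior table must align with the AMI series", call. = FALSE)
  }
  k <- floor(q * n)
  if (k < 1L) stop("floor(q * N) is zero; too few trials", call. = FALSE)
  ord <- order(series$series$ami, decreasing = TRUE)
  grp <- function(idx) {
    list(trials = idx, mean_rt = mean(behavior$rt[idx]),
         accuracy = mean(behavior$correct[idx]))
  }
  list(strong = grp(ord[seq_len(k)]),
       weak = grp(ord[seq.int(n - k + 1L, n)]),
       n_per_group = k)
}
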
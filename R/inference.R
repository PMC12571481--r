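# Permutation-based significance for decoding, group-level null
# aggregation, Bonferroni adjustment, and subject-level neural-behavior
# correlation.

new_null_distribution <- function(values, level, scheme, seed) {
  stopifnot(all(values >= 0 & values <= 1))
  structure(list(values = values, level = level, scheme = scheme,
                 n_perm = length(values), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution (", x$level, ", ", x$scheme, "): ", x$n_perm,
      " values, 95th pct ", sprintf("%.3f", quantile(x$values, 0.95)),
      "\n", sep = "")
  invisible(x)
}

# Shuffle labels within run (preserves per-run class balance).
shuffle_within_run <- function(labels, runs) {
  out <- labels
  for (r in unique(runs)) {
    idx <- which(runs == r)
    out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}

#' Subject-level permutation null distribution for decoding
#'
#' Per permutation, the training labels are shuffled within run, the FLD is
#' refit, and accuracy is measured against the unshuffled test labels.  For
#' `scheme = "within_task_loro"` the shuffle applies to the whole set and
#' the full leave-one-run-out decoder is rerun; for `scheme = "cross_task"`
#' the perception-task training labels are shuffled and the attention-task
#' test labels stay fixed.
#'
#' @param ps Attention-task [pattern_set()] (for `within_task_loro`).
#' @param scheme `"within_task_loro"` or `"cross_task"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; identical seeds give identical distributions.
#' @param shrinkage Covariance regularization intensity.
#' @param train,test Perception / attention pattern sets (for
#'   `cross_task`).
#' @return A `null_distribution` with `level = "subject"`.
#' @export
permutation_null <- function(ps = NULL, scheme = c("within_task_loro",
                                                   "cross_task"),
                             n_perm = 1000, seed = 1L, shrinkage = 0.1,
                             train = NULL, test = NULL) {
  scheme <- match.arg(scheme)
  stop_if_not_count(n_perm, "n_perm")
  if (scheme == "within_task_loro") {
    stopifnot(inherits(ps, "pattern_set"))
    x <- ps$matrix
    labels <- as.character(ps$meta$orientation)
    runs <- ps$meta$run
    classes <- sort(unique(labels))
    folds <- loro_fold_indices(runs)
    fold_n <- vapply(folds, function(f) length(f$test), numeric(1))
    values <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- shuffle_within_run(labels, runs)
        acc <- vapply(folds, function(f) {
          ytr <- perm[f$train]
          if (length(unique(ytr)) < 2L) return(NA_real_)
          core <- fld_core(x[f$train, , drop = FALSE],
                           ytr == classes[1], shrinkage)
          dv <- x[f$test, , drop = FALSE] %*% core$w + core$bias
          pred <- ifelse(dv >= 0, classes[1], classes[2])
          mean(pred == labels[f$test])
        }, numeric(1))
        sum(acc * fold_n, na.rm = TRUE) / sum(fold_n[!is.na(acc)])
      }, numeric(1))
    })
  } else {
    stopifnot(inherits(train, "pattern_set"), inherits(test, "pattern_set"))
    x <- train$matrix
    labels <- as.character(train$meta$orientation)
    runs <- train$meta$run
    classes <- sort(unique(labels))
    test_x <- test$matrix
    test_y <- as.character(test$meta$orientation)
    values <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- shuffle_within_run(labels, runs)
        if (length(unique(perm)) < 2L) return(0.5)
        core <- fld_core(x, perm == classes[1], shrinkage)
        dv <- test_x %*% core$w + core$bias
        pred <- ifelse(dv >= 0, classes[1], classes[2])
        mean(pred == test_y)
      }, numeric(1))
    })
  }
  new_null_distribution(values, "subject", scheme, as.integer(seed))
}

#' Group-level null distribution
#'
#' Element-wise mean of the per-subject null distributions at each
#' permutation index, giving one group null of the same length.
#'
#' @param subject_nulls List of subject-level `null_distribution`s with
#'   equal `n_perm`.
#' @return A `null_distribution` with `level = "group"`.
#' @export
group_null <- function(subject_nulls) {
  stopifnot(is.list(subject_nulls), length(subject_nulls) >= 1L)
  lens <- vapply(subject_nulls, function(nd) nd$n_perm, 1L)
  if (length(unique(lens)) != 1L) {
    stop("subject null distributions have mismatched lengths", call. = FALSE)
  }
  vals <- rowMeans(vapply(subject_nulls, `[[`, numeric(lens[1]), "values"))
  new_null_distribution(vals, "group", subject_nulls[[1]]$scheme,
                        subject_nulls[[1]]$seed)
}

#' Permutation p-value against a group null
#'
#' Add-one convention: `p = (1 + #(null >= observed)) / (1 + n_perm)`, so p
#' is never exactly zero.  Significance additionally follows the
#' 95th-percentile decision rule (`observed > quantile(null, 1 - alpha)`),
#' reported alongside the p-value.
#'
#' @param observed Observed (group mean) accuracy.
#' @param null A group-level `null_distribution`.
#' @param alpha Decision level for the percentile rule.
#' @return A list: `p`, `significant`, `threshold` (the null percentile),
#'   `observed`.
#' @export
permutation_pvalue <- function(observed, null, alpha = 0.05) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$n_perm < 1L) stop("empty null distribution", call. = FALSE)
  p <- (1 + sum(null$values >= observed)) / (1 + null$n_perm)
  thr <- as.numeric(quantile(null$values, 1 - alpha))
  list(p = p, significant = observed > thr, threshold = thr,
       observed = observed)
}

#' Bonferroni adjustment
#'
#' @param pvals Vector of p-values.
#' @param m Number of comparisons; defaults to the length of `pvals`, but
#'   can be supplied explicitly (e.g., the number of ROIs when adjusting one
#'   family member at a time).
#' @return `min(1, p * m)` per element.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stop_if_not_count(m, "m")
  pmin(1, pvals * m)
}

#' Inter-subject neural-behavior correlation
#'
#' Pearson correlation (two-sided) between a per-subject neural summary
#' (e.g., AMI) and a per-subject behavioral summary (RT or accuracy),
#' paired by subject id.
#'
#' @param neural,behavior Named numeric vectors keyed by subject id.
#' @return A list: `r`, `p`, `n`.
#' @export
neural_behavior_correlation <- function(neural, behavior) {
  if (is.null(names(neural)) || is.null(names(behavior)) ||
      !setequal(names(neural), names(behavior))) {
    stop("`neural` and `behavior` must be named by the same subjects",
         call. = FALSE)
  }
  behavior <- behavior[names(neural)]
  if (length(neural) < 3L) stop("need >= 3 subjects", call. = FALSE)
  ct <- stats::cor.test(neural, behavior, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(neural))
}
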
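# Fisher linear discriminant decoding with leave-one-run-out
# cross-validation and cross-task generalization.

# Shrinkage-regularized pooled within-class covariance:
#   Sigma_hat = (1 - alpha) * S + alpha * (tr(S) / V) * I
# with S the pooled (n - 2 denominator) within-class covariance.
shrunk_pooled_cov <- function(x, is_class1, alpha) {
  v <- ncol(x)
  n <- nrow(x)
  m1 <- colMeans(x[is_class1, , drop = FALSE])
  m2 <- colMeans(x[!is_class1, , drop = FALSE])
  xc <- x
  xc[is_class1, ] <- sweep(x[is_class1, , drop = FALSE], 2L, m1)
  xc[!is_class1, ] <- sweep(x[!is_class1, , drop = FALSE], 2L, m2)
  s <- crossprod(xc) / (n - 2L)
  sig <- (1 - alpha) * s
  diag(sig) <- diag(sig) + alpha * sum(diag(s)) / v
  list(sigma = sig, m1 = m1, m2 = m2)
}

# Core FLD solve shared by user-facing fit and the permutation fast path.
fld_core <- function(x, is_class1, alpha) {
  cs <- shrunk_pooled_cov(x, is_class1, alpha)
  w <- tryCatch(solve(cs$sigma, cs$m1 - cs$m2), error = function(e) {
    stop("pooled covariance is singular; increase `shrinkage`",
         call. = FALSE)
  })
  bias <- -sum(w * (cs$m1 + cs$m2)) / 2
  list(w = w, bias = bias, m1 = cs$m1, m2 = cs$m2, sigma = cs$sigma)
}

#' Fit a Fisher linear discriminant
#'
#' Weights are `w = Sigma_hat^-1 (mu_1 - mu_2)` with the shrinkage-regularized
#' pooled within-class covariance `Sigma_hat = (1-alpha) S + alpha (tr S / V) I`;
#' the bias places the decision boundary midway between the projected class
#' means (equal priors, as the design is balanced by construction).
#'
#' @param x Numeric matrix (trials x voxels) or a [pattern_set()].
#' @param labels Two-class labels, one per trial (ignored if `x` is a
#'   pattern set with an `orientation` column).
#' @param shrinkage Regularization intensity `alpha` in `[0, 1]`.
#' @return An object of class `fld_model`: `w`, `bias`, `classes` (ordered;
#'   positive decision values map to the first), `shrinkage`, `n_per_class`,
#'   and the condition number of the regularized covariance.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, 1), 20), matrix(rnorm(40, -1), 20))
#' m <- fld_fit(x, rep(c("a", "b"), each = 20))
#' fld_predict(m, x)$labels[1:3]
fld_fit <- function(x, labels = NULL, shrinkage = 0.1) {
  if (inherits(x, "pattern_set")) {
    if (is.null(labels)) labels <- x$meta$orientation
    x <- x$matrix
  }
  stopifnot(is.matrix(x), !is.null(labels), length(labels) == nrow(x))
  if (shrinkage < 0 || shrinkage > 1) {
    stop("`shrinkage` must lie in [0, 1]", call. = FALSE)
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) {
    stop("exactly two classes required, got ", length(classes),
         call. = FALSE)
  }
  is1 <- labels == classes[1]
  if (sum(is1) < 2L || sum(!is1) < 2L) {
    stop("need >= 2 trials per class", call. = FALSE)
  }
  core <- fld_core(x, is1, shrinkage)
  structure(
    list(w = core$w, bias = core$bias, classes = classes,
         shrinkage = shrinkage, n_per_class = c(sum(is1), sum(!is1)),
         cov_condition = kappa(core$sigma, exact = FALSE)),
    class = "fld_model"
  )
}

#' Predict with a Fisher linear discriminant
#'
#' Labels by the sign of `w . x + bias`; a decision value of exactly 0 is
#' assigned deterministically to the first class in the model's label order.
#'
#' @param model An [fld_fit()] model.
#' @param x Numeric matrix or [pattern_set()] with matching voxel count.
#' @return A list: `labels` (character) and `decision_values`.
#' @export
fld_predict <- function(model, x) {
  stopifnot(inherits(model, "fld_model"))
  if (inherits(x, "pattern_set")) x <- x$matrix
  if (ncol(x) != length(model$w)) {
    stop("voxel count mismatch: model has ", length(model$w),
         ", data has ", ncol(x), call. = FALSE)
  }
  dv <- drop(x %*% model$w + model$bias)
  list(labels = ifelse(dv >= 0, model$classes[1], model$classes[2]),
       decision_values = dv)
}

# Lean LORO accuracy used by both the user-facing decoder and the
# permutation null: x/labels/runs as plain vectors, no object overhead.
loro_fold_indices <- function(runs) {
  ids <- sort(unique(runs))
  lapply(ids, function(r) list(run = r, test = which(runs == r),
                               train = which(runs != r)))
}

loro_accuracies <- function(x, labels, folds, classes, alpha) {
  vapply(folds, function(f) {
    ytr <- labels[f$train]
    if (length(unique(ytr)) < 2L) {
      stop("training fold (held-out run ", f$run, ") is missing a class",
           call. = FALSE)
    }
    core <- fld_core(x[f$train, , drop = FALSE], ytr == classes[1], alpha)
    dv <- x[f$test, , drop = FALSE] %*% core$w + core$bias
    pred <- ifelse(dv >= 0, classes[1], classes[2])
    mean(pred == labels[f$test])
  }, numeric(1))
}

new_decoding_result <- function(scheme, fold_runs, fold_n, fold_acc) {
  pooled <- sum(fold_acc * fold_n) / sum(fold_n)
  structure(
    list(scheme = scheme,
         folds = data.frame(run = fold_runs, n = fold_n,
                            accuracy = fold_acc),
         pooled_accuracy = pooled),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding [", x$scheme, "]: pooled accuracy ",
      sprintf("%.3f", x$pooled_accuracy), " over ", nrow(x$folds),
      " fold(s)\n", sep = "")
  invisible(x)
}

#' Leave-one-run-out decoding of a pattern set
#'
#' For each run, fits an FLD on all other runs and tests on the held-out
#' run; the pooled accuracy is the proportion of correctly classified trials
#' over all folds (trial-weighted).
#'
#' @param ps A [pattern_set()] whose meta has `run` and `orientation`.
#' @param shrinkage Covariance regularization intensity.
#' @return A `decoding_result` with `scheme = "within_task_loro"`, per-fold
#'   accuracies and the pooled accuracy.
#' @export
loro_decode <- function(ps, shrinkage = 0.1) {
  stopifnot(inherits(ps, "pattern_set"))
  runs <- ps$meta$run
  if (length(unique(runs)) < 2L) {
    stop("need >= 2 runs for leave-one-run-out decoding", call. = FALSE)
  }
  labels <- as.character(ps$meta$orientation)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required",
                                  call. = FALSE)
  folds <- loro_fold_indices(runs)
  acc <- loro_accuracies(ps$matrix, labels, folds, classes, shrinkage)
  new_decoding_result("within_task_loro",
                      vapply(folds, `[[`, numeric(1), "run"),
                      vapply(folds, function(f) length(f$test), integer(1)),
                      acc)
}

#' Cross-task generalization from perception to attention
#'
#' Trains one FLD on all (pooled) perception trials to discriminate the two
#' perceived orientations, then tests it on the attention-task trials of the
#' requested period under the label mapping perceive-left -> attend-left.
#' There is no cross-validation: training and test data come from different
#' tasks.  Both sets must be z-normalized within their own task/period
#' groups.
#'
#' @param train A perception-task [pattern_set()] (z-normalized).
#' @param test An attention-task [pattern_set()] (z-normalized) whose meta
#'   `period` is `"preparation"` or `"selection"`.
#' @param shrinkage Covariance regularization intensity.
#' @return A `decoding_result` with `scheme = "cross_task"` (single fold).
#' @export
cross_task_generalize <- function(train, test, shrinkage = 0.1) {
  stopifnot(inherits(train, "pattern_set"), inherits(test, "pattern_set"))
  if (train$normalization_state != "znormalized" ||
      test$normalization_state != "znormalized") {
    stop("both pattern sets must be z-normalized within their own groups",
         call. = FALSE)
  }
  period <- unique(test$meta$period)
  if (length(period) != 1L || !period %in% c("preparation", "selection")) {
    stop("test period must be 'preparation' or 'selection'", call. = FALSE)
  }
  model <- fld_fit(train, shrinkage = shrinkage)
  pred <- fld_predict(model, test)
  acc <- mean(pred$labels == as.character(test$meta$orientation))
  new_decoding_result("cross_task", NA_real_, nrow(test$matrix), acc)
}
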
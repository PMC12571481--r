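# Run-level time-series preprocessing and trial-pattern extraction.

# Discrete cosine high-pass basis: columns cos(pi*k*(2t+1)/(2N)), k = 1..K,
# for all k whose frequency k/(2*N*TR) is below the cutoff.  Regressing these
# out (together with a linear trend) is the standard fMRI drift removal.
dct_basis <- function(n, tr, cutoff) {
  k_max <- floor(2 * n * tr * cutoff)
  if (k_max < 1L) return(matrix(0, n, 0L))
  t_idx <- seq_len(n) - 1L
  vapply(seq_len(k_max),
         function(k) cos(pi * k * (2 * t_idx + 1) / (2 * n)),
         numeric(n))
}

#' Preprocess one run of voxel time series
#'
#' Linear detrending, temporal high-pass filtering at `cutoff` Hz (discrete
#' cosine basis regression), then conversion to percent signal change by
#' dividing each voxel by its within-run mean.  The run mean is preserved
#' through detrending/filtering and is the divisor for the percent-signal
#' conversion.
#'
#' @param ts Numeric matrix, time points x voxels (raw scanner units).
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff in Hz.
#' @return A list: `ts` (time x voxels, percent signal change),
#'   `excluded_voxels` (indices flagged for a near-zero run mean and set to
#'   0), and `n_dct` (number of drift regressors removed).
#' @export
preprocess_run <- function(ts, tr = 2, cutoff = 0.01) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  n <- nrow(ts)
  m <- colMeans(ts)
  bad <- which(abs(m) < 1e-8 * max(1, max(abs(ts))))
  x <- cbind(1, seq_len(n), dct_basis(n, tr, cutoff))
  # residual of the drift model, with the run mean added back
  beta <- qr.coef(qr(x), ts)
  filt <- ts - x %*% beta
  filt <- sweep(filt, 2L, m, "+")
  psc <- 100 * (sweep(filt, 2L, m, "/") - 1)
  if (length(bad)) psc[, bad] <- 0
  list(ts = psc, excluded_voxels = bad, n_dct = ncol(x) - 2L)
}

#' Extract trial patterns from a run time series
#'
#' Averages, per trial and voxel, the samples whose acquisition onset falls
#' in the half-open window `[onset + window[1], onset + window[2])` seconds
#' after the event (sample-onset timing convention; with a 2-s TR and the
#' default 4-6 s window this selects exactly one volume).
#'
#' @param ts Numeric matrix, time x voxels (typically the output of
#'   [preprocess_run()]).
#' @param events Data frame with an `onset` column (seconds from run start)
#'   plus any trial metadata to carry into the pattern set.
#' @param roi ROI name for the resulting pattern set.
#' @param tr Repetition time in seconds.
#' @param window Two-element window (seconds after event onset).
#' @return A [pattern_set()] with one row per event, metadata carried
#'   through.
#' @export
extract_trial_patterns <- function(ts, events, roi = "ROI", tr = 2,
                                   window = c(4, 6)) {
  stopifnot(is.matrix(ts), is.data.frame(events), "onset" %in% names(events))
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be an increasing pair of seconds", call. = FALSE)
  }
  sample_onsets <- (seq_len(nrow(ts)) - 1L) * tr
  rows <- lapply(seq_len(nrow(events)), function(i) {
    lo <- events$onset[i] + window[1]
    hi <- events$onset[i] + window[2]
    idx <- which(sample_onsets >= lo & sample_onsets < hi)
    if (!length(idx)) {
      stop(sprintf(
        "event %d (onset %.2f s): no samples in window [%.2f, %.2f)",
        i, events$onset[i], lo, hi), call. = FALSE)
    }
    colMeans(ts[idx, , drop = FALSE])
  })
  pattern_set(roi = roi, matrix = do.call(rbind, rows), meta = events)
}

#' Filter trials by delay, correctness, and run-level accuracy
#'
#' Implements the trial-exclusion rules of the design: whole runs with
#' behavioral accuracy below `min_run_accuracy` are dropped first; then
#' attention trials are kept only when `delay == "long"` and
#' `correct == TRUE`, while perception trials are filtered on correctness
#' only.
#'
#' @param ps A [pattern_set()] whose meta has `task`, `run`, `correct`, and
#'   (for attention trials) `delay`.
#' @param min_run_accuracy Runs below this proportion correct are removed
#'   wholesale (computed over all trials of the run before trial filtering).
#' @return The filtered [pattern_set()]; attribute `"filter_log"` records
#'   counts per condition and dropped runs.
#' @export
filter_trials <- function(ps, min_run_accuracy = 0.5) {
  stopifnot(inherits(ps, "pattern_set"))
  meta <- ps$meta
  need <- c("task", "run", "correct")
  if (!all(need %in% names(meta))) {
    stop("meta must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  run_acc <- tapply(meta$correct, meta$run, mean)
  bad_runs <- as.integer(names(run_acc)[run_acc < min_run_accuracy])
  keep <- !(meta$run %in% bad_runs)
  is_att <- meta$task == "attention"
  keep <- keep & meta$correct &
    ifelse(is_att, !is.na(meta$delay) & meta$delay == "long", TRUE)
  if (!any(keep)) stop("no trials left after filtering", call. = FALSE)
  out <- subset_pattern_set(ps, which(keep))
  log <- list(
    n_input = nrow(meta),
    n_retained = sum(keep),
    dropped_runs = bad_runs,
    run_accuracy = as.numeric(run_acc),
    counts_by_orientation = as.list(table(out$meta$orientation))
  )
  attr(out, "filter_log") <- log
  out
}

#' Z-normalize a pattern set
#'
#' Per voxel, subtracts the mean and divides by the population SD
#' (denominator `n`), pooling both orientation conditions of the set.  The
#' caller is expected to hold one pattern set per task and period, so the
#' normalization group is the task/period group of the design.
#'
#' @param ps A [pattern_set()] with at least 2 trials.
#' @return The normalized [pattern_set()] (`normalization_state` updated).
#' @export
znormalize <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  x <- ps$matrix
  if (nrow(x) < 2L) stop("need >= 2 trials to z-normalize", call. = FALSE)
  mu <- colMeans(x)
  sd_v <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  zero <- which(sd_v == 0)
  if (length(zero)) {
    stop("zero-variance voxel(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sd_v, "/")
  pattern_set(ps$roi, z, ps$meta, normalization_state = "znormalized")
}

#' Filter and normalize in one step
#'
#' Convenience wrapper used throughout the pipeline: [filter_trials()]
#' followed by [znormalize()].
#'
#' @inheritParams filter_trials
#' @return A filtered, z-normalized [pattern_set()].
#' @export
prepare_pattern_set <- function(ps, min_run_accuracy = 0.5) {
  znormalize(filter_trials(ps, min_run_accuracy))
}
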
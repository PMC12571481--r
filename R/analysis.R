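# Subject- and cohort-level orchestration of the analysis modules on
# simulated (or ingested) datasets.

# Filtered + z-normalized pattern set for one ROI/period of a dataset.
prepared_set <- function(ds, roi, period, min_run_accuracy = 0.5) {
  prepare_pattern_set(subject_pattern_set(ds, roi, period),
                      min_run_accuracy)
}

#' Analyze one subject dataset
#'
#' Runs the full per-subject analysis stack on every ROI: leave-one-run-out
#' attention decoding (preparation and selection periods), cross-task
#' generalization from perception to both attention periods, the
#' attention-to-perception Mahalanobis distance table with its AMI, and the
#' cross-validated trial-wise AMI series feeding informational
#' connectivity.  All analyses use trials retained by the design's
#' filtering rules (long-delay correct attention trials; correct perception
#' trials; runs under 50% accuracy dropped), z-normalized per task and
#' period.
#'
#' @param ds A [simulate_subject()] dataset.
#' @param shrinkage Covariance regularization intensity used throughout.
#' @param periods Attention periods to analyze.
#' @return A list: `decoding` (tidy data frame: roi, scheme, period,
#'   accuracy), `geometry` (per-ROI [distance_table()]s for the preparation
#'   period), `ami_series` (per-ROI cross-validated `ami_series`), `ic`
#'   (the informational-connectivity `ic_matrix`), `mean_bold` (control
#'   connectivity on per-trial ROI mean responses), and `behavior` (mean RT
#'   and accuracy over the analyzed attention trials).
#' @export
analyze_subject <- function(ds, shrinkage = 0.1,
                            periods = c("preparation", "selection")) {
  stopifnot(inherits(ds, "subject_dataset"))
  rois <- names(ds$patterns)
  perc <- lapply(rois, function(r) prepared_set(ds, r, "perception"))
  names(perc) <- rois
  rows <- list()
  geometry <- list()
  series <- list()
  raw_means <- list()
  for (r in rois) {
    att <- lapply(periods, function(p) prepared_set(ds, r, p))
    names(att) <- periods
    for (p in periods) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ds$subject, session = ds$session, roi = r,
        scheme = "within_task_loro", period = p,
        accuracy = loro_decode(att[[p]], shrinkage)$pooled_accuracy)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ds$subject, session = ds$session, roi = r,
        scheme = "cross_task", period = p,
        accuracy = cross_task_generalize(perc[[r]], att[[p]],
                                         shrinkage)$pooled_accuracy)
    }
    geometry[[r]] <- distance_table(att[["preparation"]], perc[[r]],
                                    shrinkage)
    series[[r]] <- trialwise_ami_crossval(att[["preparation"]], shrinkage)
    # univariate control: per-trial spatial mean of the raw preparation
    # response, same retained trials as the AMI series
    raw <- filter_trials(subject_pattern_set(ds, r, "preparation"))
    ord <- order(raw$meta$run, raw$meta$trial_index_in_run)
    raw_means[[r]] <- rowMeans(raw$matrix)[ord]
  }
  prep_meta <- prepared_set(ds, rois[1], "preparation")$meta
  behavior <- data.frame(
    subject = ds$subject, session = ds$session,
    mean_rt = mean(prep_meta$rt),
    accuracy = mean(ds$meta$attention$correct),
    n_trials = nrow(prep_meta))
  list(decoding = do.call(rbind, rows),
       geometry = geometry,
       ami_series = series,
       ic = informational_connectivity(series),
       mean_bold = mean_bold_connectivity(raw_means),
       behavior = behavior)
}

#' Analyze a simulated cohort
#'
#' Applies [analyze_subject()] to every subject-session dataset and binds
#' tidy cohort-level tables.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param shrinkage Covariance regularization intensity.
#' @param periods Attention periods to analyze.
#' @return A list of tidy data frames: `decoding` (one row per subject x
#'   session x roi x scheme x period), `geometry` (distance-table cells,
#'   D_same/D_different and AMI per subject x session x roi), `ic` (long
#'   format, one row per ROI pair), `mean_bold` (same layout), and
#'   `behavior` (per subject x session).
#' @export
analyze_cohort <- function(cohort, shrinkage = 0.1,
                           periods = c("preparation", "selection")) {
  stopifnot(inherits(cohort, "cohort"))
  dec <- list(); geo <- list(); icl <- list(); mbl <- list(); beh <- list()
  for (key in names(cohort$datasets)) {
    ds <- cohort$datasets[[key]]
    res <- analyze_subject(ds, shrinkage, periods)
    dec[[key]] <- res$decoding
    beh[[key]] <- res$behavior
    geo[[key]] <- do.call(rbind, lapply(names(res$geometry), function(r) {
      dt <- res$geometry[[r]]
      data.frame(subject = ds$subject, session = ds$session, roi = r,
                 d_same = dt$d_same, d_different = dt$d_different,
                 ami = dt$ami)
    }))
    pair_rows <- function(m, kind) {
      rois <- rownames(m$z)
      pr <- which(upper.tri(m$z), arr.ind = TRUE)
      data.frame(subject = ds$subject, session = ds$session,
                 roi_a = rois[pr[, 1]], roi_b = rois[pr[, 2]],
                 r = m$r[pr], z = m$z[pr], kind = kind)
    }
    icl[[key]] <- pair_rows(res$ic, "informational")
    mbl[[key]] <- pair_rows(res$mean_bold, "mean_bold")
  }
  list(decoding = do.call(rbind, dec), geometry = do.call(rbind, geo),
       ic = do.call(rbind, icl), mean_bold = do.call(rbind, mbl),
       behavior = do.call(rbind, beh))
}

#' Group-level decoding significance table
#'
#' For each session x ROI x scheme x period cell of a cohort decoding
#' table, tests whether the mean accuracy across subjects exceeds chance
#' (0.5) with a one-sided one-sample t-test, and Bonferroni-adjusts the
#' p-values across ROIs within each session x scheme x period family.
#'
#' @param decoding The `decoding` table from [analyze_cohort()].
#' @param m Number of comparisons for the Bonferroni adjustment
#'   (default: number of ROIs in the table).
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data frame with mean accuracy, t, df, raw and adjusted p, and a
#'   significance flag per cell.
#' @export
decoding_group_table <- function(decoding, m = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(decoding))
  if (is.null(m)) m <- length(unique(decoding$roi))
  cells <- unique(decoding[, c("session", "roi", "scheme", "period")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- decoding$session == cells$session[i] &
      decoding$roi == cells$roi[i] & decoding$scheme == cells$scheme[i] &
      decoding$period == cells$period[i]
    acc <- decoding$accuracy[sel]
    tt <- stats::t.test(acc, mu = 0.5, alternative = "greater")
    cbind(cells[i, , drop = FALSE],
          data.frame(mean_accuracy = mean(acc), n = length(acc),
                     t = unname(tt$statistic), p = tt$p.value))
  }))
  out$p_adj <- bonferroni(out$p, m = max(m, 1L))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
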
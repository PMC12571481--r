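# Voxel time-series emission: turns trial patterns into per-run BOLD series
# so the window-extraction path can be exercised end to end.

#' Canonical double-gamma HRF parameters
#'
#' Peak-delay / undershoot-delay gamma densities with a 1/6 undershoot ratio
#' (the SPM canonical shape), normalized to unit peak.
#'
#' @param peak_delay,peak_disp Shape and rate-scale of the positive lobe.
#' @param under_delay,under_disp Shape and rate-scale of the undershoot.
#' @param under_ratio Undershoot amplitude relative to the peak lobe.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, peak_disp = 1,
                       under_delay = 16, under_disp = 1,
                       under_ratio = 1 / 6) {
  structure(list(peak_delay = peak_delay, peak_disp = peak_disp,
                 under_delay = under_delay, under_disp = under_disp,
                 under_ratio = under_ratio), class = "hrf_params")
}

#' Evaluate the double-gamma HRF
#'
#' @param t Time in seconds (vector).
#' @param params An [hrf_params()] list.
#' @return HRF values, unit peak, 0 for `t < 0`.
#' @export
double_gamma_hrf <- function(t, params = hrf_params()) {
  h <- dgamma(t, shape = params$peak_delay / params$peak_disp,
              scale = params$peak_disp) -
    params$under_ratio * dgamma(t, shape = params$under_delay /
                                  params$under_disp,
                                scale = params$under_disp)
  h[t < 0] <- 0
  peak <- max(dgamma(seq(0, 30, by = 0.01),
                     shape = params$peak_delay / params$peak_disp,
                     scale = params$peak_disp))
  h / peak
}

# Run layout: assigns cue/grating/stimulus onsets within each run.
# ITIs are drawn from {3, 5, 7} s; onsets restart at 10 s in every run.
layout_run_events <- function(meta, period_events, delay_seconds) {
  meta$onset <- NULL  # replaced by the laid-out event onsets
  rows <- list()
  for (r in sort(unique(meta$run))) {
    onset <- 10
    for (i in which(meta$run == r)) {
      for (ev in period_events) {
        t_ev <- onset + if (ev == "selection") delay_seconds[i] else 0
        rows[[length(rows) + 1L]] <-
          cbind(meta[i, , drop = FALSE],
                data.frame(event = ev, onset = t_ev))
      }
      onset <- onset + max(c(0, delay_seconds[i])) + 1 +
        sample(c(3, 5, 7), 1L)
    }
  }
  do.call(rbind, rows)
}

#' Emit per-run voxel time series from a subject dataset
#'
#' Each trial event contributes `pattern * HRF(t - onset)` per voxel on top
#' of a voxel baseline; additive Gaussian sampling noise is drawn per time
#' point.  Attention trials contribute a cue event (the preparation pattern)
#' and a grating event at cue + delay (the selection pattern); perception
#' trials contribute one stimulus event.  Raw units are
#' `baseline * (1 + signal / 100)` so that [preprocess_run()] recovers the
#' percent-signal-change patterns.
#'
#' @param ds A [simulate_subject()] dataset.
#' @param hrf An [hrf_params()] list.
#' @param noise_sd SD of the additive sampling noise, percent-signal units.
#' @param baseline_range Range of per-voxel raw baselines.
#' @param seed Integer seed.
#' @return A list per task (`attention`, `perception`); each holds
#'   `runs[[roi]][[run]]` raw time x voxel matrices and an `events` table
#'   (trial metadata plus `event` and `onset` columns).
#' @export
emit_timeseries <- function(ds, hrf = hrf_params(), noise_sd = 0.5,
                            baseline_range = c(800, 1200), seed = 1L) {
  stopifnot(inherits(ds, "subject_dataset"))
  tr <- ds$config$tr_seconds
  if (tr <= 0) stop("negative or zero TR", call. = FALSE)
  with_seed(child_seed(seed, "timeseries", ds$subject, ds$session), {
    out <- list()
    for (task in c("attention", "perception")) {
      meta <- ds$meta[[task]]
      if (task == "attention") {
        delays <- ifelse(meta$delay == "long",
                         sample(c(5.5, 7.5), nrow(meta), replace = TRUE),
                         sample(c(1.5, 3.5), nrow(meta), replace = TRUE))
        events_all <- layout_run_events(meta, c("preparation", "selection"),
                                        delays)
      } else {
        events_all <- layout_run_events(meta, "perception",
                                        rep(0, nrow(meta)))
      }
      runs <- list()
      for (roi in names(ds$patterns)) {
        runs[[roi]] <- list()
        for (r in sort(unique(meta$run))) {
          ev <- events_all[events_all$run == r, , drop = FALSE]
          dur <- max(ev$onset) + 20
          n_t <- ceiling(dur / tr)
          t_samp <- (seq_len(n_t) - 1L) * tr
          v <- ds$config$n_voxels
          signal <- matrix(0, n_t, v)
          for (j in seq_len(nrow(ev))) {
            trial_row <- which(meta$run == ev$run[j] &
                               meta$trial_index_in_run ==
                                 ev$trial_index_in_run[j])
            pat <- ds$patterns[[roi]][[ev$event[j]]][trial_row, ]
            h <- double_gamma_hrf(t_samp - ev$onset[j], hrf)
            signal <- signal + h %o% pat
          }
          baseline <- runif(v, baseline_range[1], baseline_range[2])
          psc <- signal + matrix(rnorm(n_t * v, 0, noise_sd), n_t, v)
          runs[[roi]][[r]] <- sweep(1 + psc / 100, 2L, baseline, "*")
        }
      }
      out[[task]] <- list(runs = runs, events = events_all)
    }
    out
  })
}
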
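# Simulation studies that validate the pipeline against its ground-truth
# generator: type-I calibration of the permutation test, recovery of the
# dual-format signature, geometry sign recovery, connectivity coupling, and
# neural-behavior coupling.  These are the package's own reference
# experiments; the same entry points back the acceptance script.

#' Type-I calibration of the group-level permutation test
#'
#' Repeats a signal-free experiment: a small cohort is simulated with no
#' orientation signal at all (`beta_att = 0`, no ping gain), each subject's
#' preparation-period data is decoded with leave-one-run-out FLD, the
#' group-level permutation null is built from within-run label shuffles,
#' and the 95th-percentile decision rule is applied to the observed group
#' mean accuracy.  Under this null the test should reject at its nominal
#' rate.
#'
#' @param n_experiments Number of independent null experiments.
#' @param n_perm Permutations per subject null.
#' @param n_subjects Subjects per experiment.
#' @param n_voxels,n_runs,trials_per_run Size of each subject's data.
#' @param alpha Decision level of the percentile rule.
#' @param seed Master seed.
#' @return A list: `rejection_rate`, `n_experiments`, `rejections`
#'   (logical per experiment).
#' @export
study_type1_calibration <- function(n_experiments = 500, n_perm = 200,
                                    n_subjects = 4, n_voxels = 12,
                                    n_runs = 4, trials_per_run = 10,
                                    alpha = 0.05, seed = 1L) {
  cfg <- sim_config(n_subjects_per_session = n_subjects,
                    n_shared_subjects = 0, n_voxels = n_voxels,
                    rois = "V1", n_attention_runs = n_runs,
                    trials_per_attention_run = trials_per_run,
                    n_perception_runs = 1,
                    trials_per_perception_run = trials_per_run,
                    p_long_delay = 1, seed = seed)
  eff <- effect_params(lambda = c(V1 = 0), beta_att = 0,
                       accuracy_mean = 0.95)
  rejections <- vapply(seq_len(n_experiments), function(i) {
    es <- child_seed(seed, "exp", i)
    accs <- numeric(n_subjects)
    nulls <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      gt <- make_ground_truth(cfg, eff, seed = child_seed(es, "gt", s))
      ds <- simulate_subject(gt, cfg, "NoPing", sprintf("S%02d", s),
                             seed = child_seed(es, "ds", s))
      ps <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                    "preparation"))
      accs[s] <- loro_decode(ps)$pooled_accuracy
      nulls[[s]] <- permutation_null(ps, "within_task_loro",
                                     n_perm = n_perm,
                                     seed = child_seed(es, "perm", s))
    }
    permutation_pvalue(mean(accs), group_null(nulls),
                       alpha = alpha)$significant
  }, logical(1))
  list(rejection_rate = mean(rejections), n_experiments = n_experiments,
       rejections = rejections)
}

# Signature of the dual-format template in one cohort's group table:
# attention decodable everywhere in both sessions; generalization to
# preparation only in the early visual ROIs of the Ping session; and
# generalization to stimulus selection everywhere.
dual_format_signature <- function(tab, early = c("V1", "EVC"),
                                  higher = c("IPS", "PFC")) {
  cell <- function(session, scheme, period, roi) {
    tab$significant[tab$session == session & tab$scheme == scheme &
                      tab$period == period & tab$roi %in% roi]
  }
  all(cell("NoPing", "within_task_loro", "preparation",
           c(early, higher))) &&
    all(cell("Ping", "within_task_loro", "preparation",
             c(early, higher))) &&
    all(cell("NoPing", "within_task_loro", "selection",
             c(early, higher))) &&
    all(cell("Ping", "within_task_loro", "selection",
             c(early, higher))) &&
    all(cell("Ping", "cross_task", "preparation", early)) &&
    !any(cell("Ping", "cross_task", "preparation", higher)) &&
    !any(cell("NoPing", "cross_task", "preparation",
              c(early, higher))) &&
    all(cell("NoPing", "cross_task", "selection", c(early, higher))) &&
    all(cell("Ping", "cross_task", "selection", c(early, higher)))
}

#' Recovery of the dual-format signature across simulated cohorts
#'
#' Simulates study-sized cohorts (both sessions, four ROIs, the default
#' calibrated effects) and asks, per cohort, whether the group decoding
#' table shows the full qualitative signature of the dual-format template:
#' above-chance attention decoding in every ROI in both sessions and
#' periods; cross-task generalization to the preparation period only in V1
#' and EVC and only with the ping; and generalization to the stimulus
#' selection period everywhere.  Significance per cell is a one-sided
#' one-sample t-test against chance across subjects, Bonferroni-adjusted
#' over the four ROIs within each session x scheme x period family.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param config A [sim_config()]; defaults to the study-analog design.
#' @param effect An [effect_params()] object.
#' @param alpha Familywise level per family.
#' @param seed Master seed.
#' @return A list: `signature_rate`, per-cohort logical `signatures`, and
#'   the group `table` of the first cohort.
#' @export
study_dual_format <- function(n_cohorts = 20, config = sim_config(),
                              effect = effect_params(), alpha = 0.05,
                              seed = 1L) {
  signatures <- logical(n_cohorts)
  first_tab <- NULL
  for (i in seq_len(n_cohorts)) {
    coh <- simulate_cohort(config, effect,
                           seed = child_seed(seed, "cohort", i))
    res <- analyze_cohort(coh)
    tab <- decoding_group_table(res$decoding,
                                m = length(config$rois), alpha = alpha)
    if (is.null(first_tab)) first_tab <- tab
    signatures[i] <- dual_format_signature(tab)
  }
  list(signature_rate = mean(signatures), signatures = signatures,
       table = first_tab)
}

#' Sign recovery of the geometry interaction contrast
#'
#' Simulates independent subjects and records the sign of
#' `D_different - D_same` in a V1-analog ROI, with the ping gain on
#' (`lambda > 0`, Ping session) or off (`lambda = 0`).  With the gain on,
#' the contrast should be positive (matched orientations closer) in most
#' replicates; with it off, the sign should be a coin flip.
#'
#' @param n_replicates Subjects per condition.
#' @param lambda Ping gain of the V1-analog ROI when "on".
#' @param n_voxels Voxels of the simulated ROI.
#' @param seed Master seed.
#' @return A list: `sign_rate_on`, `sign_rate_off`, and the contrast
#'   vectors.
#' @export
study_geometry_recovery <- function(n_replicates = 15, lambda = 0.6,
                                    n_voxels = 100, seed = 1L) {
  cfg <- sim_config(n_subjects_per_session = 1, n_shared_subjects = 0,
                    n_voxels = n_voxels, rois = "V1", seed = seed)
  one <- function(lam, i) {
    eff <- effect_params(lambda = c(V1 = lam))
    gt <- make_ground_truth(cfg, eff, seed = child_seed(seed, lam, "gt", i))
    ds <- simulate_subject(gt, cfg, "Ping", "S01",
                           seed = child_seed(seed, lam, "ds", i))
    prep <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                    "preparation"))
    perc <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                    "perception"))
    dt <- distance_table(prep, perc)
    dt$d_different - dt$d_same
  }
  on <- vapply(seq_len(n_replicates), function(i) one(lambda, i),
               numeric(1))
  off <- vapply(seq_len(n_replicates), function(i) one(0, i), numeric(1))
  list(sign_rate_on = mean(on > 0), sign_rate_off = mean(off > 0),
       contrast_on = on, contrast_off = off)
}

#' Informational-connectivity response to the shared trial-gain coupling
#'
#' Simulates cohorts over a grid of coupling strengths `g` and summarizes,
#' per cohort, the mean informational connectivity (Fisher z) between the
#' V1- and PFC-analog ROIs and the matching mean-BOLD control
#' connectivity.  Informational connectivity should increase with `g`; the
#' mean-BOLD control should not, because the coupled gain acts on
#' mean-free pattern axes.
#'
#' @param g_grid Coupling strengths to simulate.
#' @param n_cohorts Cohorts per grid point.
#' @param n_subjects Subjects per cohort.
#' @param n_voxels Voxels per ROI.
#' @param seed Master seed.
#' @return A list of matrices (`ic`, `mean_bold`), cohorts x grid points,
#'   of cohort-mean V1-PFC Fisher-z values, plus `g_grid`.
#' @export
study_connectivity_coupling <- function(g_grid = c(0, 0.3, 0.6),
                                        n_cohorts = 10, n_subjects = 6,
                                        n_voxels = 100, seed = 1L) {
  cfg <- sim_config(n_subjects_per_session = n_subjects,
                    n_shared_subjects = 0, n_voxels = n_voxels,
                    seed = seed)
  ic <- matrix(NA_real_, n_cohorts, length(g_grid))
  mb <- matrix(NA_real_, n_cohorts, length(g_grid))
  for (k in seq_along(g_grid)) {
    eff <- effect_params(g = g_grid[k])
    for (i in seq_len(n_cohorts)) {
      z_ic <- numeric(n_subjects)
      z_mb <- numeric(n_subjects)
      for (s in seq_len(n_subjects)) {
        gt <- make_ground_truth(cfg, eff,
                                seed = child_seed(seed, k, "gt", i, s))
        ds <- simulate_subject(gt, cfg, "NoPing", sprintf("S%02d", s),
                               seed = child_seed(seed, k, "ds", i, s))
        series <- list()
        raw_means <- list()
        for (r in c("V1", "PFC")) {
          prep <- prepare_pattern_set(subject_pattern_set(ds, r,
                                                          "preparation"))
          series[[r]] <- trialwise_ami_crossval(prep)
          raw <- filter_trials(subject_pattern_set(ds, r, "preparation"))
          ord <- order(raw$meta$run, raw$meta$trial_index_in_run)
          raw_means[[r]] <- rowMeans(raw$matrix)[ord]
        }
        z_ic[s] <- informational_connectivity(series)$z["V1", "PFC"]
        z_mb[s] <- mean_bold_connectivity(raw_means)$z["V1", "PFC"]
      }
      ic[i, k] <- mean(z_ic)
      mb[i, k] <- mean(z_mb)
    }
  }
  list(ic = ic, mean_bold = mb, g_grid = g_grid)
}

#' Coupling between the sensory-like template and behavior
#'
#' Simulates Ping-session cohorts and tests both neural-behavior readouts:
#' the inter-subject correlation between V1 AMI and mean RT, and the
#' within-subject RT difference between strong-modulation (top-quartile
#' AMI) and weak-modulation (bottom-quartile) trials.  With `b_rt > 0`
#' both effects should point the expected way (negative correlation,
#' faster strong-modulation trials); with `b_rt = 0` both should sit in
#' their null bands.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_subjects Subjects per cohort.
#' @param b_rt RT-coupling slope passed to [effect_params()].
#' @param n_voxels Voxels of the simulated V1-analog ROI.
#' @param q Quantile fraction for the strong/weak split.
#' @param seed Master seed.
#' @return A list: `cor_values` (per-cohort inter-subject r),
#'   `frac_negative_cor`, `rt_diff` (per-cohort mean strong - weak RT,
#'   seconds), `mean_rt_diff`.
#' @export
study_behavior_coupling <- function(n_cohorts = 20, n_subjects = 16,
                                    b_rt = effect_params()$b_rt,
                                    n_voxels = 100, q = 0.25, seed = 1L) {
  cfg <- sim_config(n_subjects_per_session = n_subjects,
                    n_shared_subjects = 0, n_voxels = n_voxels,
                    rois = "V1", seed = seed)
  eff <- effect_params(b_rt = b_rt)
  cor_values <- numeric(n_cohorts)
  rt_diff <- numeric(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    amis <- numeric(n_subjects)
    rts <- numeric(n_subjects)
    diffs <- numeric(n_subjects)
    for (s in seq_len(n_subjects)) {
      gt <- make_ground_truth(cfg, eff,
                              seed = child_seed(seed, "gt", i, s))
      ds <- simulate_subject(gt, cfg, "Ping", sprintf("S%02d", s),
                             seed = child_seed(seed, "ds", i, s))
      prep <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                      "preparation"))
      perc <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                      "perception"))
      amis[s] <- distance_table(prep, perc)$ami
      rts[s] <- mean(prep$meta$rt)
      ser <- trialwise_ami(prep, perc)
      sw <- sort_trials_by_ami(ser, prep$meta[, c("rt", "correct")], q = q)
      diffs[s] <- sw$strong$mean_rt - sw$weak$mean_rt
    }
    cor_values[i] <- cor(amis, rts)
    rt_diff[i] <- mean(diffs)
  }
  list(cor_values = cor_values, frac_negative_cor = mean(cor_values < 0),
       rt_diff = rt_diff, mean_rt_diff = mean(rt_diff))
}
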
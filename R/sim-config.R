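#' Simulation design configuration
#'
#' Describes the study design the synthetic generator emulates: two scanning
#' sessions (no-ping and ping), an attention task with preparation and
#' stimulus-selection periods, a perception task with single gratings, four
#' regions of interest along the visual hierarchy, and the run/trial counts
#' and delay probabilities of the original design.
#'
#' Defaults reproduce the study conditions: 20 subjects per session of which
#' 14 completed both, 6 attention runs and 3 perception runs, 100 voxels per
#' ROI, 80% long-delay trials, TR of 2 s.  With 40 attention trials per run
#' (20 per orientation), a long-delay probability of 0.8 and a near-threshold
#' accuracy of 0.75, filtering leaves ~72 long-delay correct trials per
#' attention condition, matching the trial counts the analyses were built for.
#'
#' @param n_subjects_per_session Subjects scanned in each session.
#' @param n_shared_subjects Subjects who completed both sessions
#'   (must be `<= n_subjects_per_session`).
#' @param n_voxels Voxels per ROI.
#' @param rois Ordered ROI names.
#' @param n_attention_runs,n_perception_runs Runs per task.
#' @param trials_per_attention_run,trials_per_perception_run Trials per run
#'   (split evenly between the two orientations).
#' @param p_long_delay Probability that an attention trial has a long delay.
#' @param tr_seconds Repetition time in seconds.
#' @param seed Master seed for the generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects_per_session = 4, n_shared_subjects = 2)
#' cfg$rois
sim_config <- function(n_subjects_per_session = 20,
                       n_shared_subjects = 14,
                       n_voxels = 100,
                       rois = c("V1", "EVC", "IPS", "PFC"),
                       n_attention_runs = 6,
                       n_perception_runs = 3,
                       trials_per_attention_run = 40,
                       trials_per_perception_run = 40,
                       p_long_delay = 0.8,
                       tr_seconds = 2,
                       seed = 1L) {
  stop_if_not_count(n_subjects_per_session, "n_subjects_per_session")
  stop_if_not_count(n_shared_subjects, "n_shared_subjects", min = 0L)
  stop_if_not_count(n_voxels, "n_voxels", min = 2L)
  stop_if_not_count(n_attention_runs, "n_attention_runs", min = 1L)
  stop_if_not_count(n_perception_runs, "n_perception_runs", min = 1L)
  stop_if_not_count(trials_per_attention_run, "trials_per_attention_run",
                    min = 2L)
  stop_if_not_count(trials_per_perception_run, "trials_per_perception_run",
                    min = 2L)
  stop_if_not_scalar_prob(p_long_delay, "p_long_delay")
  if (n_shared_subjects > n_subjects_per_session) {
    stop("`n_shared_subjects` cannot exceed `n_subjects_per_session`",
         call. = FALSE)
  }
  if (!is.character(rois) || length(rois) < 1L || anyDuplicated(rois)) {
    stop("`rois` must be distinct ROI names", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("`tr_seconds` must be positive", call. = FALSE)
  }
  if (trials_per_attention_run %% 2L != 0L ||
      trials_per_perception_run %% 2L != 0L) {
    stop("trials per run must be even so orientations balance within run",
         call. = FALSE)
  }
  structure(
    list(
      n_subjects_per_session = as.integer(n_subjects_per_session),
      n_shared_subjects = as.integer(n_shared_subjects),
      n_voxels = as.integer(n_voxels),
      rois = rois,
      n_attention_runs = as.integer(n_attention_runs),
      n_perception_runs = as.integer(n_perception_runs),
      trials_per_attention_run = as.integer(trials_per_attention_run),
      trials_per_perception_run = as.integer(trials_per_perception_run),
      p_long_delay = p_long_delay,
      tr_seconds = tr_seconds,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Ground-truth effect parameters
#'
#' Amplitudes and gains of the generative model behind the synthetic cohorts.
#' Each preparation-period pattern is
#' `mu + eta * o * beta_att * a  +  ping * lambda * o * beta_sens * s + noise`
#' where `o` is the orientation sign, `a` the non-sensory attention axis,
#' `s` the sensory axis, and `eta = 1 + g*z + xi` a trial gain whose `z`
#' component is shared across ROIs (the coupling that informational
#' connectivity detects).  Perception patterns load only on `s`; selection
#' patterns add target and distractor sensory drive with
#' `gamma_target > gamma_distractor`.
#'
#' The single-trial SNR of the original data is not recoverable from summary
#' statistics, so the default amplitudes were calibrated once against the
#' macroscopic benchmarks of the study (attention decoding roughly 0.65-0.75,
#' cross-task generalization near chance without the impulse and modestly
#' above chance with it in early visual areas) and then frozen.
#'
#' @param beta_sens Amplitude of the sensory (perceived-orientation) signal.
#' @param beta_att Amplitude of the preparatory attention signal.
#' @param lambda Named vector of ping reactivation gains in `[0, 1]` per ROI;
#'   ROIs absent from the vector get 0.  The default places the latent
#'   sensory-like component in V1 and EVC only.
#' @param gamma_target,gamma_distractor Sensory gains during stimulus
#'   selection (`gamma_target > gamma_distractor >= 0`).
#' @param noise_scale Overall scale of the voxel noise covariance.
#' @param noise_rank Number of shared low-rank noise components per ROI.
#' @param g Shared trial-gain coupling across ROIs (>= 0).
#' @param gain_sd SD of the ROI-private trial-gain jitter `xi`.
#' @param b_rt Seconds of RT facilitation per unit of subject AMI propensity;
#'   positive values couple stronger sensory reactivation to faster responses.
#' @param rt0,rt_noise_sd RT baseline and trial noise (seconds).
#' @param rt_subject_sd SD of the subject-level RT baseline jitter (seconds);
#'   RT variance unrelated to the template keeps the inter-subject AMI-RT
#'   correlation realistic rather than near-perfect.
#' @param accuracy_mean,accuracy_sd Subject-level behavioral accuracy
#'   distribution (near-threshold task).
#' @param propensity_sd SD of the between-subject reactivation propensity;
#'   a subject's effective ping gain is `lambda * (1 + propensity + u)`.
#' @param reactivation_sd SD of the within-subject trial-to-trial
#'   reactivation fluctuation `u` (drives the strong/weak modulation
#'   contrast).
#' @return An object of class `effect_params`.
#' @export
effect_params <- function(beta_sens = 1.6,
                          beta_att = 1.1,
                          lambda = c(V1 = 0.6, EVC = 0.5),
                          gamma_target = 1.0,
                          gamma_distractor = 0.3,
                          noise_scale = 1.0,
                          noise_rank = 3L,
                          g = 0.3,
                          gain_sd = 0.25,
                          b_rt = 0.08,
                          rt0 = 0.8,
                          rt_noise_sd = 0.15,
                          rt_subject_sd = 0.03,
                          accuracy_mean = 0.75,
                          accuracy_sd = 0.04,
                          propensity_sd = 0.35,
                          reactivation_sd = 0.3) {
  if (any(lambda < 0) || any(lambda > 1)) {
    stop("`lambda` gains must lie in [0, 1]", call. = FALSE)
  }
  if (!(gamma_target > gamma_distractor) || gamma_distractor < 0) {
    stop("require `gamma_target > gamma_distractor >= 0`", call. = FALSE)
  }
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  if (noise_scale <= 0) stop("`noise_scale` must be positive", call. = FALSE)
  stop_if_not_count(noise_rank, "noise_rank", min = 0L)
  vals <- list(beta_sens = beta_sens, beta_att = beta_att, lambda = lambda,
               gamma_target = gamma_target,
               gamma_distractor = gamma_distractor,
               noise_scale = noise_scale, noise_rank = as.integer(noise_rank),
               g = g, gain_sd = gain_sd, b_rt = b_rt, rt0 = rt0,
               rt_noise_sd = rt_noise_sd, rt_subject_sd = rt_subject_sd,
               accuracy_mean = accuracy_mean,
               accuracy_sd = accuracy_sd, propensity_sd = propensity_sd,
               reactivation_sd = reactivation_sd)
  num <- vals[setdiff(names(vals), "lambda")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)), TRUE))) {
    stop("effect parameters must be finite numbers", call. = FALSE)
  }
  structure(vals, class = "effect_params")
}
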
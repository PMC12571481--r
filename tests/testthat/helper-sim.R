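# Shared fixtures: small design configurations and simulated datasets
# built in code at test time.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_session = 2, n_shared_subjects = 1,
         n_voxels = 16, rois = c("V1", "EVC", "IPS", "PFC"),
         n_attention_runs = 3, trials_per_attention_run = 12,
         n_perception_runs = 2, trials_per_perception_run = 12),
    list(...))
  do.call(sim_config, args)
}

# One-ROI config for fast decode/inference tests.
v1_config <- function(...) {
  tiny_config(rois = "V1", ...)
}

tiny_subject <- function(session = "Ping", seed = 1, config = tiny_config(),
                         effect = effect_params(), subject = "S01") {
  gt <- make_ground_truth(config, effect, seed = seed)
  simulate_subject(gt, config, session, subject, seed = seed + 1000)
}

# Deterministic effect settings that remove all trial-level randomness in
# the signal part of the generative rule (eta = 1, lambda_eff = lambda).
deterministic_effect <- function(...) {
  args <- utils::modifyList(
    list(g = 0, gain_sd = 0, propensity_sd = 0, reactivation_sd = 0),
    list(...))
  do.call(effect_params, args)
}

# A pattern set with explicit matrix/labels for classifier tests.
toy_pattern_set <- function(x, orientation, run = rep(1L, nrow(x)),
                            period = "preparation", state = "raw") {
  meta <- data.frame(
    subject = "S01", session = "NoPing",
    task = if (period == "perception") "perception" else "attention",
    period = period, run = run,
    trial_index_in_run = stats::ave(seq_len(nrow(x)), run,
                                    FUN = seq_along),
    orientation = orientation,
    delay = "long", correct = TRUE, rt = 0.8)
  pattern_set("V1", x, meta, normalization_state = state)
}

# Two well-separated Gaussian classes in v voxels.
separated_classes <- function(n_per_class = 10, v = 4, sep = 6, sd = 0.5,
                              runs = 2, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  mu <- c(rep(sep / 2, v))
  x <- rbind(matrix(rnorm(n_per_class * v, mu, sd), n_per_class, v,
                    byrow = TRUE),
             matrix(rnorm(n_per_class * v, -mu, sd), n_per_class, v,
                    byrow = TRUE))
  ori <- rep(c("leftward", "rightward"), each = n_per_class)
  run <- rep_len(seq_len(runs), 2 * n_per_class)
  ord <- order(run)
  toy_pattern_set(x[ord, , drop = FALSE], ori[ord], run = run[ord])
}
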
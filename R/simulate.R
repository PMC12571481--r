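# Synthetic cohort generation.
#
# Generative model per trial and ROI (orientation sign o in {-1, +1}):
#   preparation: x = mu + eta * o * b_att * a + ping * lambda_eff * o * b_sens * s + e
#   selection:   x = mu + eta * o * b_att * a + o * (g_t - g_d) * b_sens * s + e
#   perception:  x = mu + o * b_sens * s + e
# with e ~ N(0, diag(d) + W W'), eta = 1 + g*z + xi (z shared across ROIs
# within a trial), and lambda_eff = lambda * max(0, 1 + propensity + u) where
# u is the trial-wise reactivation fluctuation.  The ping indicator gates the
# latent sensory-like component: it contributes only in the Ping session and
# only in ROIs with lambda > 0.

draw_noise <- function(n, roi_gt) {
  v <- length(roi_gt$sigma_diag)
  e <- matrix(rnorm(n * v), n, v)
  e <- sweep(e, 2L, sqrt(roi_gt$sigma_diag), "*")
  k <- ncol(roi_gt$sigma_load)
  if (k > 0L) {
    e <- e + matrix(rnorm(n * k), n, k) %*% t(roi_gt$sigma_load)
  }
  e
}

draw_subject_params <- function(effect, seed) {
  with_seed(seed, list(
    propensity = rnorm(1, 0, effect$propensity_sd),
    accuracy = min(0.98, max(0.55,
      rnorm(1, effect$accuracy_mean, effect$accuracy_sd))),
    rt0 = effect$rt0 + rnorm(1, 0, effect$rt_subject_sd)
  ))
}

#' Simulate one subject's dataset
#'
#' Generates the full trial table and trial-by-voxel pattern matrices for one
#' subject in one session: attention task (preparation and stimulus-selection
#' periods, long and short delays, balanced orientations within run) and
#' perception task (single gratings).  Behavioral correctness is Bernoulli at
#' the subject's accuracy; RTs are coupled to the subject's reactivation
#' propensity and the trial-wise reactivation fluctuation through `b_rt`.
#'
#' @param gt A [make_ground_truth()] object.
#' @param config A [sim_config()].
#' @param session `"NoPing"` or `"Ping"`.
#' @param subject Subject identifier (character).
#' @param seed Integer seed; the dataset is bit-identical given
#'   `(gt, config, session, subject, seed)`.
#' @param subject_params Optional list with `propensity`, `accuracy`, `rt0`;
#'   supplied by [simulate_cohort()] so a subject scanned in both sessions
#'   keeps the same subject-level parameters.
#' @return An object of class `subject_dataset`: trial tables in
#'   `$meta$attention` / `$meta$perception`, matrices in
#'   `$patterns[[roi]][[period]]` (periods `preparation`, `selection`,
#'   `perception`), the ground truth, and the subject-level parameters.
#' @seealso [subject_pattern_set()] to pull out a [pattern_set()].
#' @export
simulate_subject <- function(gt, config, session, subject = "S01",
                             seed = 1L, subject_params = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  if (!session %in% c("NoPing", "Ping")) {
    stop("unknown session id: ", session, call. = FALSE)
  }
  if (gt$n_voxels != config$n_voxels) {
    stop("voxel count mismatch between ground truth and config",
         call. = FALSE)
  }
  if (!setequal(names(gt$roi), config$rois)) {
    stop("ROI names differ between ground truth and config", call. = FALSE)
  }
  eff <- gt$effect
  if (is.null(subject_params)) {
    subject_params <- draw_subject_params(eff, child_seed(seed, "params"))
  }
  ping <- session == "Ping"

  with_seed(child_seed(seed, "trials", session), {
    ## ---- attention trial table ----
    n_run <- config$n_attention_runs
    tpr <- config$trials_per_attention_run
    att <- do.call(rbind, lapply(seq_len(n_run), function(r) {
      ori <- sample(rep(c("leftward", "rightward"), tpr / 2L))
      data.frame(
        subject = subject, session = session, task = "attention",
        run = r, trial_index_in_run = seq_len(tpr), orientation = ori,
        delay = ifelse(runif(tpr) < config$p_long_delay, "long", "short"),
        stringsAsFactors = FALSE
      )
    }))
    n_att <- nrow(att)
    att$correct <- runif(n_att) < subject_params$accuracy
    u <- rnorm(n_att, 0, eff$reactivation_sd)      # trial reactivation
    z <- rnorm(n_att)                              # shared gain component
    att$rt <- pmax(0.2, subject_params$rt0 -
                     eff$b_rt * (subject_params$propensity + u) +
                     rnorm(n_att, 0, eff$rt_noise_sd))
    att$onset <- NA_real_

    ## ---- perception trial table ----
    tpp <- config$trials_per_perception_run
    perc <- do.call(rbind, lapply(seq_len(config$n_perception_runs),
                                  function(r) {
      ori <- sample(rep(c("leftward", "rightward"), tpp / 2L))
      data.frame(
        subject = subject, session = session, task = "perception",
        run = r, trial_index_in_run = seq_len(tpp), orientation = ori,
        delay = NA_character_, stringsAsFactors = FALSE
      )
    }))
    n_perc <- nrow(perc)
    perc$correct <- runif(n_perc) < subject_params$accuracy
    perc$rt <- pmax(0.2, subject_params$rt0 + rnorm(n_perc, 0,
                                                    eff$rt_noise_sd))
    perc$onset <- NA_real_

    o_att <- ifelse(att$orientation == "leftward", 1, -1)
    o_perc <- ifelse(perc$orientation == "leftward", 1, -1)
    lambda_eff <- pmax(0, 1 + subject_params$propensity + u)
    long <- att$delay == "long"

    patterns <- vector("list", length(config$rois))
    names(patterns) <- config$rois
    for (r in config$rois) {
      rg <- gt$roi[[r]]
      eta <- 1 + eff$g * z + rnorm(n_att, 0, eff$gain_sd)
      base <- matrix(rg$mu, n_att, config$n_voxels, byrow = TRUE)
      att_sig <- (eta * o_att * eff$beta_att) %o% rg$a
      # short-delay trials carry no preparation signal of interest
      prep <- base + att_sig * long + draw_noise(n_att, rg)
      if (ping && rg$lambda > 0) {
        prep <- prep +
          ((rg$lambda * lambda_eff * o_att * eff$beta_sens) * long) %o% rg$s
      }
      sel <- base + att_sig +
        (o_att * (eff$gamma_target - eff$gamma_distractor) *
           eff$beta_sens) %o% rg$s + draw_noise(n_att, rg)
      pb <- matrix(rg$mu, n_perc, config$n_voxels, byrow = TRUE)
      pp <- pb + (o_perc * eff$beta_sens) %o% rg$s + draw_noise(n_perc, rg)
      patterns[[r]] <- list(preparation = prep, selection = sel,
                            perception = pp)
    }

    structure(
      list(subject = subject, session = session,
           meta = list(attention = att, perception = perc),
           patterns = patterns, gt = gt, config = config,
           params = c(subject_params, list(seed = as.integer(seed))),
           gain = data.frame(run = att$run,
                             trial_index_in_run = att$trial_index_in_run,
                             z = z, u = u)),
      class = "subject_dataset"
    )
  })
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("Subject dataset:", x$subject, "/", x$session, "-",
      nrow(x$meta$attention), "attention +", nrow(x$meta$perception),
      "perception trials,", length(x$patterns), "ROIs\n")
  invisible(x)
}

#' Extract a pattern set from a subject dataset
#'
#' @param ds A [simulate_subject()] dataset.
#' @param roi ROI name.
#' @param period `"preparation"`, `"selection"` (attention task) or
#'   `"perception"`.
#' @return A [pattern_set()] in raw (un-normalized) units.
#' @export
subject_pattern_set <- function(ds, roi, period) {
  stopifnot(inherits(ds, "subject_dataset"))
  if (!roi %in% names(ds$patterns)) stop("unknown ROI: ", roi, call. = FALSE)
  period <- match.arg(period, c("preparation", "selection", "perception"))
  task <- if (period == "perception") "perception" else "attention"
  meta <- ds$meta[[task]]
  meta$period <- period
  pattern_set(roi = roi, matrix = ds$patterns[[roi]][[period]], meta = meta)
}

#' Simulate a cohort with partially overlapping sessions
#'
#' Draws `2 * n_subjects_per_session - n_shared_subjects` distinct subjects.
#' The first `n_shared_subjects` complete both the NoPing and Ping sessions,
#' reusing their ground truth and subject-level parameters (propensity,
#' accuracy, RT baseline) across sessions; the remainder complete exactly one
#' session.
#'
#' @param config A [sim_config()].
#' @param effect An [effect_params()] object (used by the default ground
#'   truth factory).
#' @param seed Master seed; per-subject and per-session children are derived
#'   deterministically.
#' @param gt_factory Optional `function(seed)` returning a
#'   [make_ground_truth()] object; defaults to
#'   `make_ground_truth(config, effect, seed)`.
#' @return An object of class `cohort`: `$datasets` keyed `"<subject>.<session>"`,
#'   and a `$manifest` data frame recording the overlap structure and seeds.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects_per_session = 3, n_shared_subjects = 2,
#'                   n_voxels = 12, trials_per_attention_run = 8,
#'                   n_attention_runs = 2, trials_per_perception_run = 8)
#' coh <- simulate_cohort(cfg, effect_params(), seed = 7)
#' coh$manifest
simulate_cohort <- function(config, effect = effect_params(), seed = 1L,
                            gt_factory = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gt_factory)) {
    gt_factory <- function(s) make_ground_truth(config, effect, seed = s)
  }
  n <- config$n_subjects_per_session
  n_shared <- config$n_shared_subjects
  n_total <- 2L * n - n_shared
  ids <- sprintf("S%02d", seq_len(n_total))
  sessions_of <- function(i) {
    if (i <= n_shared) c("NoPing", "Ping")
    else if (i <= n) "NoPing"
    else "Ping"
  }
  datasets <- list()
  rows <- list()
  for (i in seq_len(n_total)) {
    sid <- ids[i]
    sseed <- child_seed(seed, "subject", i)
    gt <- gt_factory(sseed)
    params <- draw_subject_params(effect, child_seed(sseed, "params"))
    for (sess in sessions_of(i)) {
      dseed <- child_seed(sseed, sess)
      datasets[[paste(sid, sess, sep = ".")]] <-
        simulate_subject(gt, config, sess, subject = sid, seed = dseed,
                         subject_params = params)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sid, session = sess,
                   shared = i <= n_shared, seed = dseed,
                   stringsAsFactors = FALSE)
    }
  }
  structure(
    list(config = config, effect = effect, seed = as.integer(seed),
         manifest = do.call(rbind, rows), datasets = datasets),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", length(unique(x$manifest$subject)), "subjects,",
      nrow(x$manifest), "subject-sessions (",
      sum(x$manifest$shared) / 2L, "in both )\n")
  invisible(x)
}
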
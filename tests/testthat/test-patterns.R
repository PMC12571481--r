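# Time-series preprocessing, window extraction, trial filtering, and
# z-normalization.

test_that("percent signal change and detrending behave on degenerate input", {
  # constant series: percent signal change is identically zero
  ts <- matrix(500, 60, 3)
  out <- preprocess_run(ts, tr = 2)
  expect_equal(out$ts, matrix(0, 60, 3), tolerance = 1e-10)

  # pure linear ramp: removed by detrending
  ramp <- matrix(1000 + 2 * seq_len(80), 80, 1)
  out <- preprocess_run(ramp, tr = 2)
  expect_lt(max(abs(out$ts)), 1e-8)
})

test_that("high-pass filter attenuation matches an independent projection oracle", {
  n <- 200; tr <- 2
  t_s <- (seq_len(n) - 1) * tr
  slow <- sin(2 * pi * 0.002 * t_s)   # below the 0.01 Hz cutoff
  fast <- sin(2 * pi * 0.05 * t_s)    # well above it
  base <- 1000
  out <- preprocess_run(cbind(base + slow, base + fast), tr = tr)
  att_slow <- sd(out$ts[, 1]) / sd(100 * slow / base)
  att_fast <- sd(out$ts[, 2]) / sd(100 * fast / base)
  expect_lt(att_slow, 0.25)
  expect_gt(att_fast, 0.9)

  # oracle: residual-maker matrix of the same regressors, built directly,
  # with the percent-signal divisor being the observed run mean
  x <- cbind(1, seq_len(n), attmvpa:::dct_basis(n, tr, 0.01))
  m_res <- diag(n) - x %*% solve(crossprod(x), t(x))
  expect_equal(sd(out$ts[, 1]),
               sd(100 * (m_res %*% slow) / mean(base + slow)),
               tolerance = 1e-10)
  expect_equal(sd(out$ts[, 2]),
               sd(100 * (m_res %*% fast) / mean(base + fast)),
               tolerance = 1e-10)
})

test_that("window extraction follows the half-open sample-onset convention", {
  # TR = 2 s, event at t = 0: only the sample acquired at 4 s is in [4, 6)
  ts <- matrix(seq_len(10), 10, 1)  # sample k acquired at (k-1)*2 s
  ev <- data.frame(onset = 0)
  ps <- extract_trial_patterns(ts, ev, tr = 2, window = c(4, 6))
  expect_equal(unname(ps$matrix[1, 1]), 3)  # sample index 3, onset 4 s

  # constant series: every trial pattern equals the constant
  ts_c <- matrix(7.5, 40, 2)
  ev2 <- data.frame(onset = c(0, 10, 20))
  ps2 <- extract_trial_patterns(ts_c, ev2, tr = 2)
  expect_true(all(ps2$matrix == 7.5))
  expect_identical(nrow(ps2$matrix), 3L)

  # event whose window is empty is named in the error
  expect_error(extract_trial_patterns(ts, data.frame(onset = c(0, 30)),
                                      tr = 2),
               "event 2")
})

test_that("extraction recovers HRF-convolved amplitudes (convolution oracle)", {
  tr <- 2; n <- 50
  t_s <- (seq_len(n) - 1) * tr
  onsets <- c(10, 40, 70)
  amps <- c(2, -1.5, 3)
  ts <- matrix(0, n, 1)
  for (i in seq_along(onsets)) {
    ts <- ts + amps[i] * double_gamma_hrf(t_s - onsets[i])
  }
  ps <- extract_trial_patterns(ts, data.frame(onset = onsets), tr = tr)
  # oracle: direct evaluation of the summed convolution at window samples
  oracle <- vapply(onsets, function(o) {
    idx <- t_s >= o + 4 & t_s < o + 6
    mean(rowSums(vapply(seq_along(onsets), function(j) {
      amps[j] * double_gamma_hrf(t_s - onsets[j])
    }, numeric(n)))[idx])
  }, numeric(1))
  expect_equal(unname(ps$matrix[, 1]), oracle, tolerance = 1e-12)
})

test_that("noiseless emitted time series matches the generative convolution", {
  cfg <- tiny_config(rois = "V1", n_voxels = 4, n_attention_runs = 1,
                     trials_per_attention_run = 4,
                     n_perception_runs = 1, trials_per_perception_run = 4)
  ds <- tiny_subject("NoPing", seed = 2, config = cfg,
                     effect = effect_params(lambda = c(V1 = 0.6)))
  em <- emit_timeseries(ds, noise_sd = 0, seed = 3)
  raw <- em$perception$runs$V1[[1]]
  ev <- em$perception$events
  # first events start at 10 s, so the first sample is pure baseline
  baseline <- raw[1, ]
  psc <- 100 * sweep(sweep(raw, 2, baseline, "/"), 2, 1)
  n <- nrow(raw)
  t_s <- (seq_len(n) - 1) * cfg$tr_seconds
  oracle <- matrix(0, n, cfg$n_voxels)
  for (j in seq_len(nrow(ev))) {
    pat <- ds$patterns$V1$perception[ev$trial_index_in_run[j], ]
    oracle <- oracle + double_gamma_hrf(t_s - ev$onset[j]) %o% pat
  }
  expect_equal(psc, oracle, tolerance = 1e-8, ignore_attr = TRUE)

  # extraction equals the window average of the oracle convolution exactly,
  # and recovers the trial patterns up to HRF scaling plus the overlap of
  # neighboring responses
  ps <- extract_trial_patterns(psc, ev, tr = cfg$tr_seconds)
  ps_oracle <- extract_trial_patterns(oracle, ev, tr = cfg$tr_seconds)
  expect_equal(ps$matrix, ps_oracle$matrix, tolerance = 1e-8)
  expect_gt(cor(as.vector(ps$matrix),
                as.vector(ds$patterns$V1$perception)), 0.8)
})

test_that("trial filtering applies delay, correctness and run-accuracy rules", {
  # synthetic composition: 90 trials, 72 long-correct, 10 long-incorrect,
  # 8 short
  n <- 90
  delay <- c(rep("long", 82), rep("short", 8))
  correct <- c(rep(TRUE, 72), rep(FALSE, 10), rep(TRUE, 8))
  x <- matrix(rnorm(n * 3), n, 3)
  meta <- data.frame(subject = "S01", session = "Ping", task = "attention",
                     period = "preparation", run = rep(1:3, each = 30),
                     trial_index_in_run = rep(1:30, 3),
                     orientation = rep_len(c("leftward", "rightward"), n),
                     delay = delay, correct = correct, rt = 0.8)
  ps <- pattern_set("V1", x, meta)
  out <- filter_trials(ps)
  # brute-force row-scan oracle
  expect_identical(nrow(out$matrix),
                   sum(delay == "long" & correct))
  expect_identical(nrow(out$matrix), 72L)
  expect_true(all(out$meta$delay == "long" & out$meta$correct))

  # idempotence
  expect_identical(filter_trials(out)$matrix, out$matrix)

  # all-correct all-long input passes through unchanged
  ps_id <- pattern_set("V1", x[1:72, ], meta[1:72, ])
  expect_identical(nrow(filter_trials(ps_id)$matrix), 72L)

  # a run at 45% accuracy is removed wholesale
  meta2 <- meta
  meta2$delay <- "long"
  meta2$correct <- TRUE
  meta2$correct[meta2$run == 2][1:17] <- FALSE  # 13/30 = 43% correct
  ps2 <- pattern_set("V1", x, meta2)
  out2 <- filter_trials(ps2)
  expect_false(any(out2$meta$run == 2))
  expect_identical(attr(out2, "filter_log")$dropped_runs, 2L)

  # everything filtered out is an explicit error
  meta3 <- meta
  meta3$correct <- FALSE
  expect_error(filter_trials(pattern_set("V1", x, meta3)),
               "no trials left")
})

test_that("z-normalization uses the population-SD convention", {
  # two-trial toy: values 1 and 3 on one voxel -> -1, +1
  ps <- toy_pattern_set(matrix(c(1, 3), 2, 1), c("leftward", "rightward"))
  z <- znormalize(ps)
  expect_equal(unname(z$matrix[, 1]), c(-1, 1))
  expect_identical(z$normalization_state, "znormalized")

  # definitional: per-voxel mean 0, population SD 1
  set.seed(5)
  x <- matrix(rnorm(60, 5, 3), 12, 5)
  z2 <- znormalize(toy_pattern_set(x, rep_len(c("leftward", "rightward"),
                                              12)))
  expect_equal(unname(colMeans(z2$matrix)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z2$matrix, 2, attmvpa:::pop_sd)), rep(1, 5),
               tolerance = 1e-12)

  # affine invariance: a*x + b normalizes to the same output
  x_aff <- sweep(sweep(x, 2, c(2, 3, 0.5, 10, 1), "*"), 2, 1:5, "+")
  z3 <- znormalize(toy_pattern_set(x_aff, rep_len(c("leftward",
                                                    "rightward"), 12)))
  expect_equal(z3$matrix, z2$matrix, tolerance = 1e-12)

  # zero-variance voxels are reported by index
  x0 <- x; x0[, 3] <- 2
  expect_error(znormalize(toy_pattern_set(x0, rep_len(c("leftward",
                                                        "rightward"), 12))),
               "zero-variance voxel\\(s\\): 3")
})
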
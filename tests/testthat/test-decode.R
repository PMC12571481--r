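# Fisher linear discriminant fitting, prediction, cross-validation and
# cross-task generalization.

test_that("FLD weights match the closed-form shrinkage solution", {
  set.seed(10)
  v <- 6; n <- 14
  x <- rbind(matrix(rnorm(n * v, 1, 1.5), n, v),
             matrix(rnorm(n * v, -1, 1.5), n, v))
  y <- rep(c("leftward", "rightward"), each = n)
  alpha <- 0.1
  m <- fld_fit(x, y, shrinkage = alpha)

  # independent closed-form computation with base cov() and solve()
  m1 <- colMeans(x[1:n, ]); m2 <- colMeans(x[(n + 1):(2 * n), ])
  s_pool <- ((n - 1) * cov(x[1:n, ]) + (n - 1) * cov(x[(n + 1):(2 * n), ])) /
    (2 * n - 2)
  sigma <- (1 - alpha) * s_pool + alpha * (sum(diag(s_pool)) / v) * diag(v)
  w0 <- solve(sigma, m1 - m2)
  expect_equal(m$w, w0, tolerance = 1e-10)
  expect_equal(m$bias, -sum(w0 * (m1 + m2)) / 2, tolerance = 1e-10)

  # identity covariance: weights parallel to the mean difference
  set.seed(11)
  xs <- rbind(matrix(rnorm(4000, 3, 1), 200, 20),
              matrix(rnorm(4000, -3, 1), 200, 20))
  ms <- fld_fit(xs, rep(c("a", "b"), each = 200), shrinkage = 0)
  dmu <- colMeans(xs[1:200, ]) - colMeans(xs[201:400, ])
  cosine <- sum(ms$w * dmu) / sqrt(sum(ms$w^2) * sum(dmu^2))
  expect_gt(cosine, 0.98)

  # separable two-trials-per-class case: training points on correct side
  x2 <- matrix(c(2, 2.5, -2, -2.5), 4, 1)
  m2c <- fld_fit(x2, c("a", "a", "b", "b"), shrinkage = 0.5)
  pr <- fld_predict(m2c, x2)
  expect_identical(pr$labels, c("a", "a", "b", "b"))

  expect_error(fld_fit(x2, rep("a", 4)), "two classes")
  expect_error(fld_fit(x2, c("a", "b", "b", "b")), ">= 2 trials")
})

test_that("prediction is the sign of the decision value with a deterministic tie rule", {
  ps <- separated_classes(n_per_class = 8, seed = 12)
  m <- fld_fit(ps)
  # batch predictions equal an independently computed w.x + bias sign
  dv0 <- drop(ps$matrix %*% m$w + m$bias)
  pr <- fld_predict(m, ps)
  expect_equal(pr$decision_values, dv0)
  expect_identical(pr$labels,
                   ifelse(dv0 >= 0, m$classes[1], m$classes[2]))

  # a test point at the class-1 training mean is classified as class 1
  mu1 <- colMeans(ps$matrix[ps$meta$orientation == "leftward", ])
  expect_identical(fld_predict(m, matrix(mu1, 1))$labels, "leftward")

  # decision value exactly 0 goes to the first-listed class
  m_manual <- structure(list(w = c(1, 0), bias = 0,
                             classes = c("leftward", "rightward"),
                             shrinkage = 0.1, n_per_class = c(2L, 2L),
                             cov_condition = 1),
                        class = "fld_model")
  pr_tie <- fld_predict(m_manual, matrix(c(0, 5), 1))
  expect_identical(pr_tie$decision_values, 0)
  expect_identical(pr_tie$labels, "leftward")

  # positive rescaling of the discriminant leaves predictions unchanged
  m_scaled <- m; m_scaled$w <- 7 * m$w; m_scaled$bias <- 7 * m$bias
  expect_identical(fld_predict(m_scaled, ps)$labels, pr$labels)

  expect_error(fld_predict(m, matrix(0, 1, 2)), "voxel count mismatch")
})

test_that("leave-one-run-out decoding pools fold accuracies trial-weighted", {
  cfg <- tiny_config(n_attention_runs = 6)
  ds <- tiny_subject("NoPing", seed = 13, config = cfg)
  ps <- prepare_pattern_set(subject_pattern_set(ds, "V1", "preparation"))
  res <- loro_decode(ps)
  expect_identical(nrow(res$folds), 6L)  # one fold per run
  expect_identical(sum(res$folds$n), nrow(ps$matrix))
  expect_equal(res$pooled_accuracy,
               sum(res$folds$accuracy * res$folds$n) / sum(res$folds$n))
  expect_true(res$pooled_accuracy >= 0 && res$pooled_accuracy <= 1)

  # noiseless separable data decodes perfectly
  ps_sep <- separated_classes(n_per_class = 12, sep = 10, sd = 0.2,
                              runs = 3, seed = 14)
  expect_equal(loro_decode(ps_sep)$pooled_accuracy, 1.0)

  # shuffling trial order (with labels) leaves the accuracies unchanged
  set.seed(15)
  perm <- sample.int(nrow(ps$matrix))
  ps_perm <- pattern_set(ps$roi, ps$matrix[perm, ], ps$meta[perm, ],
                         ps$normalization_state)
  expect_equal(loro_decode(ps_perm)$pooled_accuracy, res$pooled_accuracy)

  # labels independent of patterns: accuracy inside the binomial null band
  set.seed(16)
  n <- 120
  x <- matrix(rnorm(n * 10), n, 10)
  ps_null <- toy_pattern_set(x, sample(rep(c("leftward", "rightward"),
                                           n / 2)),
                             run = rep(1:4, each = n / 4))
  acc <- loro_decode(ps_null)$pooled_accuracy
  expect_true(abs(acc - 0.5) < 1.96 * sqrt(0.25 / n) + 1e-9)

  # a training fold missing a class names the fold
  ps_bad <- toy_pattern_set(matrix(rnorm(24), 12, 2),
                            c(rep("leftward", 8), rep("rightward", 4)),
                            run = c(rep(1L, 4), rep(2L, 4), rep(3L, 4)))
  expect_error(loro_decode(ps_bad), "missing a class")
})

test_that("small-instance LORO equals a brute-force FLD reimplementation", {
  # oracle: explicit fold loop with the textbook formula, <=10 voxels
  set.seed(17)
  for (rep_i in 1:3) {
    n <- 36; v <- 8
    x <- matrix(rnorm(n * v), n, v) +
      outer(rep_len(c(1, -1), n), rnorm(v, 0, 0.5))
    y <- rep_len(c("leftward", "rightward"), n)
    run <- rep(1:3, each = 12)
    alpha <- 0.1
    oracle_correct <- 0
    for (r in 1:3) {
      tr <- run != r; te <- run == r
      m1 <- colMeans(x[tr & y == "leftward", ])
      m2 <- colMeans(x[tr & y == "rightward", ])
      xc <- rbind(sweep(x[tr & y == "leftward", ], 2, m1),
                  sweep(x[tr & y == "rightward", ], 2, m2))
      s <- crossprod(xc) / (sum(tr) - 2)
      sig <- (1 - alpha) * s + alpha * mean(diag(s)) * diag(v)
      w <- solve(sig, m1 - m2)
      b <- -sum(w * (m1 + m2)) / 2
      pred <- ifelse(x[te, ] %*% w + b >= 0, "leftward", "rightward")
      oracle_correct <- oracle_correct + sum(pred == y[te])
    }
    ps <- toy_pattern_set(x, y, run = run)
    expect_equal(loro_decode(ps, shrinkage = alpha)$pooled_accuracy,
                 oracle_correct / n, tolerance = 1e-12)
  }
})

test_that("cross-task generalization trains once on pooled perception runs", {
  cfg <- tiny_config()
  eff_ping <- effect_params()
  ds <- tiny_subject("Ping", seed = 18, config = cfg, effect = eff_ping)
  perc <- prepare_pattern_set(subject_pattern_set(ds, "V1", "perception"))
  prep <- prepare_pattern_set(subject_pattern_set(ds, "V1", "preparation"))
  sel <- prepare_pattern_set(subject_pattern_set(ds, "V1", "selection"))

  # strong stimulus drive: selection period generalizes well above chance
  expect_gt(cross_task_generalize(perc, sel)$pooled_accuracy, 0.6)

  # degenerate self-test (train = test) is at least as accurate as the
  # held-out decoding of the same data (optimism property)
  self_acc <- cross_task_generalize(perc, {
    p2 <- perc; p2$meta$period <- "selection"; p2$meta$task <- "attention"
    p2
  })$pooled_accuracy
  expect_gte(self_acc, loro_decode(perc)$pooled_accuracy)

  # normalization and period contracts are enforced
  raw <- subject_pattern_set(ds, "V1", "preparation")
  expect_error(cross_task_generalize(perc, filter_trials(raw)),
               "z-normalized")
  bad_period <- prep; bad_period$meta$period <- "perception"
  expect_error(cross_task_generalize(perc, bad_period),
               "'preparation' or 'selection'")

  # no-ping preparation (latent component gated off) stays near chance
  ds0 <- tiny_subject("NoPing", seed = 18, config = cfg, effect = eff_ping)
  perc0 <- prepare_pattern_set(subject_pattern_set(ds0, "V1", "perception"))
  prep0 <- prepare_pattern_set(subject_pattern_set(ds0, "V1",
                                                   "preparation"))
  acc0 <- cross_task_generalize(perc0, prep0)$pooled_accuracy
  n0 <- nrow(prep0$matrix)
  expect_true(abs(acc0 - 0.5) < 2.6 * sqrt(0.25 / n0))
})

test_that("cross-task generalization accuracy rises with the ping gain", {
  cfg <- tiny_config(rois = "V1", n_voxels = 40,
                     trials_per_attention_run = 20,
                     trials_per_perception_run = 20)
  lam_grid <- c(0, 0.25, 0.5, 1)
  med_acc <- vapply(lam_grid, function(lam) {
    accs <- vapply(1:9, function(i) {
      eff <- effect_params(lambda = c(V1 = lam))
      gt <- make_ground_truth(cfg, eff, seed = 100 * i)
      ds <- simulate_subject(gt, cfg, "Ping", "S01", seed = 100 * i + 1)
      perc <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                      "perception"))
      prep <- prepare_pattern_set(subject_pattern_set(ds, "V1",
                                                      "preparation"))
      cross_task_generalize(perc, prep)$pooled_accuracy
    }, numeric(1))
    median(accs)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= 0))
  expect_gt(med_acc[4], med_acc[1])
})
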
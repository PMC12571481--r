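# Mahalanobis distances, the 2x2 attention x perception table, and the
# attentional modulation index.

# Reference set whose sample mean is 0 and sample covariance (n-1
# denominator after within-condition centering) is exactly diag(d).
exact_cov_ref <- function(d) {
  base <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  sweep(base, 2, sqrt(3 * d) / 2, "*")
}

test_that("Mahalanobis distance reduces to analytic cases", {
  # identity covariance: d((3,4), 0) = 5
  ref_i <- exact_cov_ref(c(1, 1))
  expect_equal(mahalanobis_to_distribution(c(3, 4), ref_i, shrinkage = 0),
               5, tolerance = 1e-10)
  # the reference mean itself is at distance 0
  expect_equal(mahalanobis_to_distribution(colMeans(ref_i), ref_i,
                                           shrinkage = 0), 0)
  # diagonal covariance diag(4, 1): d((2,1), 0) = sqrt(2)
  ref_d <- exact_cov_ref(c(4, 1))
  expect_equal(mahalanobis_to_distribution(c(2, 1), ref_d, shrinkage = 0),
               sqrt(2), tolerance = 1e-10)
  # a singular unregularized covariance recommends shrinkage
  sing <- matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE)
  expect_error(mahalanobis_to_distribution(c(0, 0), rbind(sing, sing),
                                           shrinkage = 0),
               "shrinkage")
  expect_error(mahalanobis_to_distribution(c(0, 0),
                                           matrix(1, 1, 2)), ">= 2 trials")
})

test_that("AMI obeys its algebraic identities exactly", {
  expect_identical(ami(1, 1), 0)
  expect_identical(ami(0, 2), 1)
  expect_identical(ami(2, 0), -1)
  expect_identical(ami(1, 3), 0.5)
  # antisymmetry under swapping same/different
  for (pair in list(c(0.3, 1.7), c(2, 5), c(0.01, 0.02))) {
    expect_equal(ami(pair[1], pair[2]), -ami(pair[2], pair[1]))
  }
  expect_error(ami(0, 0), "both distances are zero")
  expect_error(ami(-1, 2), "non-negative")
})

test_that("distance table matches a brute-force double-loop oracle", {
  set.seed(30)
  v <- 5
  alpha <- 0.1
  perc_x <- rbind(matrix(rnorm(5 * v, 1), 5, v),
                  matrix(rnorm(5 * v, -1), 5, v))
  perc <- toy_pattern_set(perc_x, rep(c("leftward", "rightward"), each = 5),
                          period = "perception", state = "znormalized")
  att_x <- matrix(rnorm(10 * v), 10, v)
  att <- toy_pattern_set(att_x, rep_len(c("leftward", "rightward"), 10),
                         state = "znormalized")
  dt <- distance_table(att, perc, shrinkage = alpha)

  # oracle: explicit covariance pooling and per-trial loop
  refs <- list(leftward = perc_x[1:5, ], rightward = perc_x[6:10, ])
  xc <- rbind(sweep(refs$leftward, 2, colMeans(refs$leftward)),
              sweep(refs$rightward, 2, colMeans(refs$rightward)))
  s <- crossprod(xc) / (10 - 2)
  sig <- (1 - alpha) * s + alpha * mean(diag(s)) * diag(v)
  sig_inv <- solve(sig)
  d_cell <- matrix(0, 2, 2,
                   dimnames = list(c("leftward", "rightward"),
                                   c("leftward", "rightward")))
  counts <- d_cell
  for (i in 1:10) {
    a_ori <- att$meta$orientation[i]
    for (p_ori in c("leftward", "rightward")) {
      delta <- att_x[i, ] - colMeans(refs[[p_ori]])
      d <- sqrt(drop(t(delta) %*% sig_inv %*% delta))
      d_cell[a_ori, p_ori] <- d_cell[a_ori, p_ori] + d
      counts[a_ori, p_ori] <- counts[a_ori, p_ori] + 1
    }
  }
  d_cell <- d_cell / counts
  expect_equal(dt$cells, d_cell, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dt$d_same, mean(c(d_cell[1, 1], d_cell[2, 2])))
  expect_equal(dt$d_different, mean(c(d_cell[1, 2], d_cell[2, 1])))
  expect_equal(dt$ami, (dt$d_different - dt$d_same) /
                 (dt$d_different + dt$d_same))
})

test_that("distances are invariant under a common orthogonal rotation", {
  set.seed(31)
  v <- 6
  perc_x <- rbind(matrix(rnorm(8 * v, 1.5), 8, v),
                  matrix(rnorm(8 * v, -1.5), 8, v))
  att_x <- matrix(rnorm(6 * v), 6, v)
  q <- qr.Q(qr(matrix(rnorm(v * v), v, v)))
  mk <- function(px, ax) {
    perc <- toy_pattern_set(px, rep(c("leftward", "rightward"), each = 8),
                            period = "perception", state = "znormalized")
    att <- toy_pattern_set(ax, rep_len(c("leftward", "rightward"), 6),
                           state = "znormalized")
    distance_table(att, perc)
  }
  dt1 <- mk(perc_x, att_x)
  dt2 <- mk(perc_x %*% q, att_x %*% q)
  expect_equal(dt1$cells, dt2$cells, tolerance = 1e-8)
})

test_that("geometry recovers the latent template direction", {
  cfg <- tiny_config(rois = "V1", n_voxels = 40,
                     trials_per_attention_run = 20,
                     trials_per_perception_run = 20)
  # strong ping gain, modest noise: matched orientations are closer
  eff <- effect_params(lambda = c(V1 = 1), noise_scale = 0.7)
  gt <- make_ground_truth(cfg, eff, seed = 40)
  ds <- simulate_subject(gt, cfg, "Ping", "S01", seed = 41)
  prep <- prepare_pattern_set(subject_pattern_set(ds, "V1", "preparation"))
  perc <- prepare_pattern_set(subject_pattern_set(ds, "V1", "perception"))
  dt <- distance_table(prep, perc)
  expect_lt(dt$d_same, dt$d_different)
  expect_gt(dt$ami, 0)

  # lambda = 0 with orthogonal axes: interaction contrast near 0 on average
  eff0 <- effect_params(lambda = c(V1 = 0))
  contrasts <- vapply(1:8, function(i) {
    gt0 <- make_ground_truth(cfg, eff0, seed = 50 + i)
    ds0 <- simulate_subject(gt0, cfg, "NoPing", "S01", seed = 60 + i)
    p0 <- prepare_pattern_set(subject_pattern_set(ds0, "V1", "preparation"))
    pc0 <- prepare_pattern_set(subject_pattern_set(ds0, "V1", "perception"))
    d <- distance_table(p0, pc0)
    d$d_different - d$d_same
  }, numeric(1))
  expect_gt(t.test(contrasts)$p.value, 0.01)
})

test_that("trial-wise AMI tracks the trial's own reference assignment", {
  set.seed(32)
  v <- 4
  perc_x <- rbind(matrix(rnorm(6 * v, 2), 6, v),
                  matrix(rnorm(6 * v, -2), 6, v))
  perc <- toy_pattern_set(perc_x, rep(c("leftward", "rightward"), each = 6),
                          period = "perception", state = "znormalized")
  # one attention trial exactly at the leftward reference mean
  mu_l <- colMeans(perc_x[1:6, ])
  att <- toy_pattern_set(rbind(mu_l, matrix(rnorm(3 * v), 3, v)),
                         c("leftward", "rightward", "leftward",
                           "rightward"),
                         state = "znormalized")
  ser <- trialwise_ami(att, perc)
  expect_identical(nrow(ser$series), 4L)       # bookkeeping
  expect_equal(ser$series$ami[1], 1)           # d_same = 0 for that trial

  # mean of trial-wise AMI agrees in sign with the table-level AMI
  cfg <- tiny_config(rois = "V1", n_voxels = 30)
  eff <- effect_params(lambda = c(V1 = 1), noise_scale = 0.7)
  gt <- make_ground_truth(cfg, eff, seed = 70)
  ds <- simulate_subject(gt, cfg, "Ping", "S01", seed = 71)
  prep <- prepare_pattern_set(subject_pattern_set(ds, "V1", "preparation"))
  perc2 <- prepare_pattern_set(subject_pattern_set(ds, "V1", "perception"))
  ser2 <- trialwise_ami(prep, perc2)
  dt2 <- distance_table(prep, perc2)
  expect_gt(mean(ser2$series$ami) * dt2$ami, 0)
})

test_that("AMI-based trial sorting splits by quantile with correct summaries", {
  vals <- c(0.5, -0.2, 0.9, 0.1, -0.7, 0.3, 0.0, 0.6)
  ser <- attmvpa:::new_ami_series(
    vals,
    data.frame(run = rep(1:2, each = 4), trial_index_in_run = rep(1:4, 2),
               orientation = rep_len(c("leftward", "rightward"), 8)),
    "V1", "perception_ref")
  beh <- data.frame(rt = seq(0.5, 1.2, by = 0.1), correct = rep(c(TRUE,
                                                                  FALSE), 4))
  out <- sort_trials_by_ami(ser, beh, q = 0.25)
  expect_identical(out$n_per_group, 2)  # floor(0.25 * 8)
  # top two AMI values are 0.9 (trial 3) and 0.6 (trial 8)
  expect_setequal(out$strong$trials, c(3L, 8L))
  expect_equal(out$strong$mean_rt, mean(beh$rt[c(3, 8)]))
  # bottom two are -0.7 (trial 5) and -0.2 (trial 2)
  expect_setequal(out$weak$trials, c(5L, 2L))
  expect_equal(out$weak$accuracy, mean(beh$correct[c(5, 2)]))
  expect_error(sort_trials_by_ami(ser, beh, q = 0.02), "too few trials")
  expect_error(sort_trials_by_ami(ser, beh[1:3, ]), "align")
})
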
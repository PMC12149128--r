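test_that("mask thresholding is strict", {
  expect_identical(detect_mask(c(0, 1, 2, 3), 1.5)$values, c(0L, 0L, 1L, 1L))
  e <- runif(50)
  expect_identical(detect_mask(e, min(e) - 1)$values, rep(1L, 50))
  expect_identical(detect_mask(e, max(e))$values, rep(0L, 50))
  expect_error(detect_mask(e, Inf), "finite")
})

test_that("threshold grid spans mu +/- 3 sd in 121 symmetric steps", {
  set.seed(31)
  e <- rnorm(500, 10, 2)
  g <- build_threshold_grid(e)
  expect_length(g$values, 121)
  expect_equal(min(g$values), g$mu - 3 * g$sd)
  expect_equal(max(g$values), g$mu + 3 * g$sd)
  expect_equal(unique(round(diff(g$values), 12)), round(0.05 * g$sd, 12))
  expect_equal(g$values + rev(g$values), rep(2 * g$mu, 121))
  expect_true(all(diff(g$values) > 0))
  expect_error(build_threshold_grid(rep(1, 10)), "sd is zero")
})

test_that("perfectly separated energies give grid AUC 1", {
  truth <- ehg_mask(rep(c(0L, 1L), each = 50), fs = 5)
  e <- c(runif(50, 0, 1), runif(50, 10, 11))
  roc <- roc_against_mask(e, truth)
  expect_equal(roc$auc, 1.0)
  expect_gt(roc$youden_j, 0.999)
  expect_error(roc_against_mask(e, ehg_mask(rep(1L, 100), fs = 5)),
               "both classes")
})

test_that("energies independent of truth give AUC near one half", {
  set.seed(32)
  aucs <- replicate(200, {
    e <- rexp(200)
    truth <- ehg_mask(sample(rep(c(0L, 1L), each = 100)), fs = 5)
    roc_against_mask(e, truth)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("a small printed fixture reproduces the rank-statistic AUC", {
  e <- c(2, 4, 6, 8, 10, 12, 1, 3, 5, 7, 9, 11)
  truth <- ehg_mask(rep(c(1L, 0L), each = 6), fs = 5)
  expect_equal(rank_auc(e, truth), oracle_auc(e, truth$values))
  expect_equal(roc_against_mask(e, truth)$auc, oracle_auc(e, truth$values))
})

test_that("grid AUC tracks exact rank AUC within the grid-resolution bound", {
  set.seed(33)
  for (rep in 1:50) {
    n <- 300
    truth_v <- rbinom(n, 1, 0.4)
    e <- rnorm(n) + truth_v * runif(1, 0, 2)
    truth <- ehg_mask(truth_v, fs = 5)
    expect_lt(abs(roc_against_mask(e, truth)$auc - rank_auc(e, truth)), 0.02)
  }
})

test_that("monotone transforms preserve rank AUC exactly and grid AUC within 0.02", {
  set.seed(34)
  truth_v <- rbinom(400, 1, 0.3)
  e <- abs(rnorm(400) + truth_v * 1.2)
  truth <- ehg_mask(truth_v, fs = 5)
  for (f in list(function(x) x^2, sqrt, function(x) 5 * x + 2, log1p)) {
    expect_equal(rank_auc(f(e), truth), rank_auc(e, truth), tolerance = 1e-12)
    expect_lt(abs(roc_against_mask(f(e), truth)$auc -
                    roc_against_mask(e, truth)$auc), 0.02)
  }
})

test_that("optimal threshold maximizes Youden J, ties resolving downward", {
  e <- rep(1:4, each = 25)
  truth <- ehg_mask(rep(c(0L, 0L, 1L, 1L), each = 25), fs = 5)
  roc <- roc_against_mask(e, truth)
  # any threshold in [2, 3) achieves J = 1; the lowest grid value must win
  cand <- roc$thresholds[abs((roc$tpr - roc$fpr) - roc$youden_j) < 1e-12]
  expect_equal(roc$optimal_threshold, min(cand))
  m <- detect_mask(e, roc$optimal_threshold)
  expect_identical(m$values, truth$values)
})

test_that("channel AUC map reflects distance to the contraction origin", {
  sim <- make_suite("low_snr", seed = 41, n_channels = 12,
                    n_recordings = 1)[[1]]
  pipe <- run_detection_pipeline(sim)
  amap <- channel_auc_map(pipe$fast, pipe$mask, pipe$layout)
  att <- pipe$truth$attenuation[amap$channel_id]
  near <- amap$auc[which.max(att)]
  far <- amap$auc[which.min(att)]
  expect_gt(near, far)
  expect_true(all(c("x", "y", "z") %in% names(amap)))

  # duplicated channel gives an identical AUC (determinism)
  rec2 <- ehg_recording(pipe$fast$data[c(1, 1), ], pipe$fast$fs,
                        c("dup1", "dup2"))
  a2 <- channel_auc_map(rec2, pipe$mask)
  expect_identical(a2$auc[1], a2$auc[2])
})

test_that("all-noise channels score near-chance AUC", {
  set.seed(35)
  truth <- truth_mask(
    list(intervals = data.frame(start_s = c(100, 300, 600, 900, 1500),
                                end_s = c(160, 380, 680, 960, 1560))),
    5, 2000)
  aucs <- replicate(40, {
    roc_against_mask(window_energy(rnorm(10000)), truth)$auc
  })
  expect_gte(mean(aucs >= 0.35 & aucs <= 0.65), 0.95)
})
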
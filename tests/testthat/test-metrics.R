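test_that("window energy handles constants, zeros, and impulses", {
  e <- window_energy(rep(1, 200), n = 50)
  expect_equal(e[100], 51)                     # full centered window: n+1 ones
  expect_equal(window_energy(rep(0, 50)), rep(0, 50))
  x <- rep(0, 200); x[80] <- 3
  e <- window_energy(x, n = 50)
  expect_equal(e[abs(seq_len(200) - 80) <= 25], rep(9, 51))
  expect_equal(e[abs(seq_len(200) - 80) > 25], rep(0, 149))
})

test_that("window energy equals the brute-force window sum", {
  set.seed(21)
  for (rep in 1:30) {
    x <- rnorm(sample(20:300, 1))
    n <- sample(2:60, 1)
    expect_equal(window_energy(x, n), oracle_energy(x, n), tolerance = 1e-11)
  }
})

test_that("quantile trimming discards the spike tail per the interpolation rule", {
  kept <- suppressMessages(trim_energies(1:100, 0.95))
  expect_length(kept, 95)
  expect_true(all(kept <= 95.05))
  const <- suppressMessages(trim_energies(rep(4, 30)))
  expect_length(const, 30)
  expect_identical(suppressMessages(trim_energies(c(1:10, 1:10), 0.5)),
                   c(1:5, 1:5))
  expect_error(trim_energies(1:30, 1.2), "between 0 and 1")
  expect_error(trim_energies(1:10, 0.95), "at least 20")
})

test_that("skewness matches closed forms and is scale invariant", {
  expect_equal(energy_skewness(c(1, 2, 3)), 0)
  expect_equal(energy_skewness(c(0, 0, 0, 1)), 2 / sqrt(3))
  set.seed(22)
  e <- rexp(100)
  expect_equal(energy_skewness(7.3 * e), energy_skewness(e), tolerance = 1e-12)
  expect_error(energy_skewness(rep(2, 10)), "sd = 0")
})

test_that("kurtosis is the plain (non-excess) fourth moment", {
  expect_equal(energy_kurtosis(c(-1, 1, -1, 1)), 1)
  set.seed(23)
  g <- rnorm(1e5)
  expect_equal(energy_kurtosis(g), 3, tolerance = 0.05)
  e <- rexp(100)
  expect_equal(energy_kurtosis(5 * e), energy_kurtosis(e), tolerance = 1e-12)
})

test_that("PAER matches direct evaluation and is a pure ratio metric", {
  expect_equal(paer(rep(3, 10)), 0)
  expect_equal(paer(c(1, 10)), 20 * log10(10 / 5.5))
  set.seed(24)
  e <- rexp(50)
  expect_equal(paer(100 * e), paer(e), tolerance = 1e-10)
  expect_error(paer(rep(0, 10)), "not positive")
})

test_that("moments agree with a two-pass oracle to 1e-12", {
  set.seed(25)
  for (rep in 1:50) {
    e <- rexp(sample(10:200, 1)) + runif(1, 0, 5)
    expect_equal(energy_skewness(e), oracle_skewness(e), tolerance = 1e-12)
    expect_equal(energy_kurtosis(e), oracle_kurtosis(e), tolerance = 1e-12)
  }
})

test_that("shifting energy mass toward zero with the top tail fixed never lowers PAER", {
  set.seed(26)
  for (rep in 1:20) {
    e <- rexp(200) + 0.1
    cutoff <- quantile(e, 0.95)
    shrunk <- e
    low <- e < cutoff
    shrunk[low] <- e[low] * runif(sum(low), 0, 1)   # top 5% untouched
    expect_gte(paer(shrunk), paer(e) - 1e-12)
  }
})

test_that("channel metrics increase under enhancement on a high-contrast channel", {
  set.seed(27)
  n <- 3000
  burst <- rep(c(0, 1, 0, 1, 0), c(1100, 150, 700, 150, 900))
  f <- rnorm(n, sd = 0.5) + burst * rnorm(n)        # noisy fast wave
  s <- burst * 2 + 0.1                              # slow amplitude tracks bursts
  enh <- enhance_signal(f, s)
  mf <- channel_metrics(f); me <- channel_metrics(enh)
  expect_gt(me$skewness, mf$skewness)
  expect_gt(me$kurtosis, mf$kurtosis)
  expect_gt(me$paer, mf$paer)
})

test_that("pure-noise energy metrics sit in the near-Gaussian baseline regime", {
  # window energies of white noise are ~ scaled chi^2_51 (skewness 0.40,
  # kurtosis ~3.2); discarding the top 5% pulls skewness down and kurtosis
  # below 3, so the sanity band brackets the trimmed chi^2 regime
  set.seed(28)
  sk <- ku <- numeric(20)
  for (i in 1:20) {
    m <- channel_metrics(rnorm(3000))
    sk[i] <- m$skewness; ku[i] <- m$kurtosis
  }
  expect_gt(median(sk), -0.6); expect_lt(median(sk), 0.8)
  expect_gt(median(ku), 2); expect_lt(median(ku), 4)
  expect_error(channel_metrics(rep(1, 100)), "sd = 0")
})

test_that("recording_metrics yields one labelled row per channel", {
  set.seed(29)
  rec <- ehg_recording(matrix(rnorm(600), 3), fs = 5)
  tab <- recording_metrics(rec)
  expect_identical(tab$channel_id, rec$channel_ids)
  expect_identical(tab$band, rep("raw", 3))
  expect_true(all(tab$n_used >= 2))
})
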
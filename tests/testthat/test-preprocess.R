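# Band-splitting uses fs = 64 Hz in most cases to keep series short; the
# design itself is also checked at the native 2048 Hz rate where the
# normalized cutoffs are extreme.

make_sine <- function(f_hz, fs, dur_s, amp = 1) {
  amp * sin(2 * pi * f_hz * (0:(dur_s * fs - 1)) / fs)
}

test_that("slow band preserves in-band tones and rejects out-of-band tones", {
  fs <- 64
  x <- make_sine(0.05, fs, 1200)
  rec <- ehg_recording(matrix(x, 1), fs = fs)
  y <- channel_series(bandpass(rec, slow_band()), 1)
  trim <- (200 * fs):(1000 * fs)            # transient-free interior
  a_in <- fft_amplitude(y[trim], fs, 0.05)
  expect_gt(a_in, 0.99); expect_lt(a_in, 1.01)

  x2 <- make_sine(0.6, fs, 1200)
  y2 <- channel_series(bandpass(ehg_recording(matrix(x2, 1), fs = fs),
                                slow_band()), 1)
  a_out <- fft_amplitude(y2[trim], fs, 0.6)
  expect_lt(20 * log10(a_out / 1), -20)
})

test_that("filtering zeros gives zeros and the filter is linear", {
  fs <- 64
  rec0 <- ehg_recording(matrix(0, 1, 4096), fs = fs)
  expect_equal(channel_series(bandpass(rec0, fast_band()), 1), rep(0, 4096))

  set.seed(3)
  x <- rnorm(4096); y <- rnorm(4096)
  f <- function(v) channel_series(
    bandpass(ehg_recording(matrix(v, 1), fs = fs), fast_band()), 1)
  lhs <- f(2.5 * x - 1.25 * y)
  rhs <- 2.5 * f(x) - 1.25 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
})

test_that("forward-backward filtering is zero-phase for a band-centered tone", {
  fs <- 64
  x <- make_sine(0.583, fs, 600)           # geometric center of 0.34-1 Hz
  y <- channel_series(bandpass(ehg_recording(matrix(x, 1), fs = fs),
                               fast_band()), 1)
  trim <- (100 * fs):(500 * fs)
  cc <- stats::ccf(y[trim], x[trim], lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("SOS design matches the reference transfer-function design at moderate cutoffs", {
  skip_if_not_installed("signal")
  fs <- 64
  ref <- signal::butter(4, c(1, 4) / (fs / 2), type = "pass")
  sos <- ehgkit:::butter_bandpass_sos(1, 4, fs, 4L)
  f <- seq(0.2, 10, by = 0.2)
  z <- exp(1i * 2 * pi * f / fs)
  h_sos <- Reduce(`*`, lapply(sos, function(s)
    (s$b[1] * z^2 + s$b[2] * z + s$b[3]) / (z^2 + s$a[2] * z + s$a[3])))
  h_ref <- vapply(z, function(zz)
    sum(ref$b * zz^(length(ref$b):1 - 1)) / sum(ref$a * zz^(length(ref$a):1 - 1)),
    complex(1))
  expect_lt(max(abs(abs(h_sos) - abs(h_ref))), 1e-8)
})

test_that("passbands above Nyquist are rejected", {
  rec <- ehg_recording(matrix(rnorm(100), 1), fs = 1.5)
  expect_error(bandpass(rec, fast_band()), "Nyquist")
})

test_that("polyphase resampling has the specified length, DC and tone accuracy", {
  r <- ehg_recording(matrix(rnorm(2048), 1), fs = 2048)
  expect_identical(n_samples(resample_to(r, 5)), 5L)
  expect_error(resample_to(r, 4096), "strictly below")

  rc <- ehg_recording(matrix(rep(2.25, 3 * 2048), 1), fs = 2048)
  yc <- channel_series(resample_to(rc, 5), 1)
  expect_lt(max(abs(yc - 2.25)), 1e-6)

  fs_in <- 2048
  x <- make_sine(0.05, fs_in, 120)
  y <- channel_series(resample_to(ehg_recording(matrix(x, 1), fs = fs_in), 5), 1)
  t_out <- (seq_along(y) - 1) / 5
  interior <- t_out > 15 & t_out < 105
  expect_lt(max(abs(y - sin(2 * pi * 0.05 * t_out))[interior]), 1e-3)
})

test_that("channel screening keeps the closed 0.01-0.3 mV fast-wave band", {
  fs <- 5
  mk <- function(amp) amp * sin(2 * pi * 0.6 * (0:599) / fs)
  rec <- ehg_recording(rbind(mk(0.5), mk(0.005), mk(0.1)), fs = fs,
                       band = "raw")
  rec$band <- "fast"                        # synthetic already-filtered series
  q <- suppressMessages(screen_channels(rec))
  expect_identical(q$keep, c(FALSE, FALSE, TRUE))

  # scaling a recording by 10 flips keep for channels whose max crosses a bound
  set.seed(11)
  for (rep in 1:20) {
    amp <- runif(1, 0.001, 0.05)
    r1 <- ehg_recording(matrix(mk(amp), 1), fs = fs); r1$band <- "fast"
    r2 <- ehg_recording(matrix(10 * mk(amp), 1), fs = fs); r2$band <- "fast"
    q1 <- suppressMessages(screen_channels(r1))
    q2 <- suppressMessages(screen_channels(r2))
    expect_identical(q1$keep, q1$max_abs_fast >= 0.01 & q1$max_abs_fast <= 0.3)
    expect_identical(q2$keep, q2$max_abs_fast >= 0.01 & q2$max_abs_fast <= 0.3)
    expect_equal(q2$max_abs_fast, 10 * q1$max_abs_fast, tolerance = 1e-12)
  }
})
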
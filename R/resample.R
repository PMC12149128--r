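# Rational polyphase resampling. The EHG pipeline needs 2048 Hz -> 5 Hz,
# a non-integer factor 5/2048, so the resampler upsamples by p, applies a
# windowed-sinc lowpass at the common rate, and keeps every q-th sample --
# without ever materializing the upsampled series. Each of the p phase
# filters is normalized to unit DC gain so constants survive exactly away
# from the edges.

resample_kernel <- function(p, q, halfwidth_periods = 10L, beta = 5) {
  m <- max(p, q)
  nh <- halfwidth_periods * m               # half-width at the up-rate
  t <- seq(-nh, nh)
  h <- ifelse(t == 0, 1 / m, sin(pi * t / m) / (pi * t))
  w <- besselI(beta * sqrt(pmax(0, 1 - (t / nh)^2)), 0) / besselI(beta, 0)
  list(h = h * w, nh = nh)
}

resample_series <- function(x, p, q) {
  n <- length(x)
  ker <- resample_kernel(p, q)
  h <- ker$h; nh <- ker$nh
  n_out <- ceiling(n * p / q)
  y <- numeric(n_out)
  for (m in seq_len(n_out) - 1L) {
    up <- m * q                              # position at the common rate
    i_lo <- max(0L, ceiling((up - nh) / p))
    i_hi <- min(n - 1L, floor((up + nh) / p))
    idx <- i_lo:i_hi
    taps <- h[up - p * idx + nh + 1L]
    y[m + 1L] <- sum(x[idx + 1L] * taps) / sum(taps)
  }
  y
}

#' Resample a recording to a lower rate
#'
#' Polyphase rational resampling by the reduced factor `fs_out/fs(rec)`.
#' Intended for band-limited series (both EHG bands sit far below the 2.5 Hz
#' Nyquist limit of the standard 5 Hz working rate), so decimation loses no
#' information. Output sample `m` sits at time `m / fs_out`; the output
#' length is `ceiling(N * fs_out / fs_in)`.
#'
#' @param rec an [ehg_recording()].
#' @param fs_out target rate in Hz, strictly below `rec$fs`.
#' @return An `ehg_recording` at `fs_out` with the same band tag.
#' @examples
#' rec <- ehg_recording(matrix(sin(2 * pi * 0.05 * (0:4095) / 64), 1), fs = 64)
#' resample_to(rec, 5)
#' @export
resample_to <- function(rec, fs_out) {
  stopifnot(inherits(rec, "ehg_recording"))
  if (fs_out >= rec$fs)
    stop("fs_out must be strictly below the recording rate", call. = FALSE)
  frac <- fs_out / rec$fs
  # rational approximation: fs values are rationals in practice (5/2048 etc.)
  den <- round(rec$fs * 1e6); num <- round(fs_out * 1e6)
  g <- gcd_int(num, den)
  p <- num / g; q <- den / g
  out <- t(apply(rec$data, 1L, resample_series, p = p, q = q))
  if (n_channels(rec) == 1L) out <- matrix(out, nrow = 1L)
  ehg_recording(out, fs_out, rec$channel_ids, band = rec$band, meta = rec$meta)
}

gcd_int <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Standard preprocessing: band-split, downsample, screen
#'
#' Convenience wrapper running the canonical EHG front end: zero-phase
#' Butterworth band-splitting at the native rate into slow (0.01--0.1 Hz)
#' and fast (0.34--1 Hz) waves, polyphase downsampling of both to
#' `fs_out` (5 Hz by default), and fast-wave quality screening.
#'
#' @param rec raw [ehg_recording()].
#' @param slow,fast [band_spec()]s for the two bands.
#' @param fs_out working rate in Hz after downsampling.
#' @return list with elements `slow`, `fast` (5 Hz recordings, all channels)
#'   and `quality` (data.frame from [screen_channels()]).
#' @export
preprocess_recording <- function(rec, slow = slow_band(), fast = fast_band(),
                                 fs_out = 5) {
  s <- resample_to(bandpass(rec, slow), fs_out)
  f <- resample_to(bandpass(rec, fast), fs_out)
  q <- screen_channels(f)
  list(slow = s, fast = f, quality = q)
}
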
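#' Band-pass filter specification
#'
#' Describes a Butterworth band-pass. The two bands of interest for uterine
#' EHG are the slow wave (0.01--0.1 Hz, large-amplitude, noise-robust) and
#' the fast wave (0.34--1 Hz, the conventional contraction-monitoring band).
#'
#' @param low_hz,high_hz passband edges in Hz, `0 < low_hz < high_hz`.
#' @param order analog prototype order (default 4). Zero-phase filtering
#'   doubles the effective attenuation order.
#' @return A `band_spec` list.
#' @examples
#' band_spec(0.34, 1)
#' @export
band_spec <- function(low_hz, high_hz, order = 4L) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 family = "butterworth"),
            class = "band_spec")
}

#' Slow- and fast-wave band presets
#' @return A `band_spec` for the 0.01--0.1 Hz slow wave or the 0.34--1 Hz
#'   fast wave.
#' @export
slow_band <- function() band_spec(0.01, 0.1, 4L)

#' @rdname slow_band
#' @export
fast_band <- function() band_spec(0.34, 1, 4L)

# Butterworth band-pass in second-order sections via the bilinear transform.
# Transfer-function polynomial coefficients underflow catastrophically at the
# normalized cutoffs this package needs (0.01 Hz at fs = 2048 Hz is 1e-5 of
# Nyquist), so the design stays in zero-pole-gain form and is only ever
# realized as cascaded biquads.
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 4L) {
  if (high_hz >= fs / 2)
    stop(sprintf("passband edge %g Hz is at or above Nyquist (%g Hz)",
                 high_hz, fs / 2), call. = FALSE)
  n <- as.integer(order)
  # prewarped analog edges
  wl <- 2 * fs * tan(pi * low_hz / fs)
  wh <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # analog lowpass prototype poles on the unit left half circle
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each prototype pole splits into two
  pb <- bw * p_lp / 2
  disc <- sqrt(pb^2 - w0^2)
  p_bp <- c(pb + disc, pb - disc)      # 2n analog poles
  # analog zeros: n at s = 0; gain bw^n
  # bilinear transform (fs2 = 2*fs)
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  # digital zeros: n at z = 1 (from s = 0), n at z = -1 (degree deficit);
  # gain from H(s) = (bw*s)^n / prod(s - p): each pole factor contributes
  # 1/(fs2 - p), each analog zero at 0 contributes fs2
  k_d <- abs(Re(bw^n * fs2^n / prod(fs2 - p_bp)))
  # pair conjugate poles into biquads, innermost (closest to unit circle) last
  half <- p_d[Im(p_d) >= 0]
  half <- half[order(abs(1 - abs(half)))]
  g_sec <- k_d^(1 / n)
  sos <- lapply(half, function(p) {
    a <- c(1, -2 * Re(p), abs(p)^2)
    b <- g_sec * c(1, 0, -1)           # one zero at +1, one at -1
    list(b = b, a = a)
  })
  sos
}

# single biquad, zero initial state; FIR part vectorized, AR part in C
biquad_filter <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  if (n > 1L) v[-1] <- v[-1] + b[2] * x[-n]
  if (n > 2L) v[-c(1L, 2L)] <- v[-c(1L, 2L)] + b[3] * x[seq_len(n - 2L)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (sec in sos) x <- biquad_filter(x, sec$b, sec$a)
  x
}

# Zero-phase forward-backward filtering with odd-symmetric edge extension.
# The pad length scales with the slowest time constant of the band so that
# start-up transients from the 0.01 Hz edge decay inside the padding.
sos_filtfilt <- function(x, sos, pad = NULL) {
  n <- length(x)
  if (n < 4L) stop("series too short to filter", call. = FALSE)
  if (is.null(pad)) pad <- min(n - 1L, 10L * length(sos) * 3L)
  pad <- min(n - 1L, as.integer(pad))
  if (pad > 0L) {
    head_ext <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xe <- c(head_ext, x, tail_ext)
  } else xe <- x
  y <- sos_filter(xe, sos)
  y <- rev(sos_filter(rev(y), sos))
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)] else y
  y
}

#' Band-split a raw recording with a zero-phase Butterworth filter
#'
#' Applies a fourth-order (by default) Butterworth band-pass forward and
#' backward (zero phase, so contraction timing is not shifted relative to a
#' TOCO mask), realized as cascaded second-order sections for numerical
#' stability at the very low normalized cutoffs that arise when filtering
#' 0.01 Hz content at a native 2048 Hz sampling rate.
#'
#' @param rec a raw [ehg_recording()].
#' @param spec a [band_spec()]; [slow_band()] and [fast_band()] are the
#'   standard EHG choices.
#' @return An `ehg_recording` tagged `"slow"` or `"fast"` (any other band is
#'   tagged `"raw"` with the passband stored in `meta`). `meta$edge_s`
#'   flags the first/last 30 s as potentially transient-contaminated.
#' @examples
#' rec <- ehg_recording(matrix(rnorm(4096), nrow = 1), fs = 64)
#' slow <- bandpass(rec, slow_band())
#' @export
bandpass <- function(rec, spec) {
  stopifnot(inherits(rec, "ehg_recording"), inherits(spec, "band_spec"))
  if (rec$band != "raw")
    stop("bandpass() expects a raw recording", call. = FALSE)
  sos <- butter_bandpass_sos(spec$low_hz, spec$high_hz, rec$fs, spec$order)
  # 3 time constants of the lower band edge, capped at the series length
  pad <- ceiling(3 * rec$fs / (2 * pi * spec$low_hz))
  out <- t(apply(rec$data, 1L, sos_filtfilt, sos = sos, pad = pad))
  band <- if (isTRUE(all.equal(c(spec$low_hz, spec$high_hz), c(0.01, 0.1)))) "slow"
          else if (isTRUE(all.equal(c(spec$low_hz, spec$high_hz), c(0.34, 1)))) "fast"
          else "raw"
  meta <- rec$meta
  meta$band_hz <- c(spec$low_hz, spec$high_hz)
  meta$edge_s <- 30
  ehg_recording(out, rec$fs, rec$channel_ids, band = band, meta = meta)
}

#' Screen channels for fast-wave quality
#'
#' Electrodes whose fast-wave peak magnitude exceeds 0.3 mV (motion/contact
#' artifact) or falls below 0.01 mV (poor coupling) are flagged as
#' low-quality and excluded from downstream analysis. The bounds form a
#' closed keep-interval; the peak is measured after trimming three filter
#' time-constants at each end so filter transients do not decide a
#' channel's fate.
#'
#' @param fast a fast-band [ehg_recording()] (any rate; screening is usually
#'   run on the 5 Hz series).
#' @param min_mv,max_mv keep-interval bounds in mV.
#' @return A data.frame (`channel_id`, `max_abs_fast`, `keep`).
#' @export
screen_channels <- function(fast, min_mv = 0.01, max_mv = 0.3) {
  stopifnot(inherits(fast, "ehg_recording"))
  if (fast$band != "fast")
    stop("screen_channels() expects a fast-band recording", call. = FALSE)
  n <- n_samples(fast)
  trim <- min((n - 1L) %/% 2L, ceiling(3 * fast$fs / (2 * pi * 0.34)))
  idx <- (trim + 1L):(n - trim)
  mx <- apply(abs(fast$data[, idx, drop = FALSE]), 1L, max)
  keep <- mx >= min_mv & mx <= max_mv
  message(sprintf("channel quality: %d/%d kept", sum(keep), length(keep)))
  data.frame(channel_id = fast$channel_ids, max_abs_fast = as.numeric(mx),
             keep = keep, stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep only quality-screened channels
#' @param rec an [ehg_recording()].
#' @param quality data.frame from [screen_channels()].
#' @return The recording restricted to `keep == TRUE` channels.
#' @export
apply_screen <- function(rec, quality) {
  keep_ids <- quality$channel_id[quality$keep]
  i <- match(keep_ids, rec$channel_ids)
  if (anyNA(i)) stop("quality table names channels absent from recording",
                     call. = FALSE)
  ehg_recording(rec$data[i, , drop = FALSE], rec$fs, keep_ids,
                band = rec$band, meta = rec$meta)
}
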
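#' Sliding-window signal energy
#'
#' Sum of squared samples over the same centered, edge-truncated windows as
#' [rms_envelope()], stride one sample. The energy series is the common
#' substrate for both the quality metrics and the threshold detector: its
#' histogram separates into a baseline-noise mode and a contraction mode,
#' and everything downstream measures or exploits that separation.
#'
#' @param x numeric series (fast wave in mV or enhanced signal in mV^2).
#' @param n window length in samples (default 50 = 10 s at 5 Hz). A full
#'   interior window holds `n + 1` samples.
#' @return nonnegative numeric series, same length as `x`.
#' @examples
#' window_energy(rep(1, 200))[100]  # interior window of 51 ones
#' @export
window_energy <- function(x, n = 50L) {
  if (length(x) < 1L) stop("empty series", call. = FALSE)
  windowed_sum_sq(as.numeric(x), as.integer(n))$sum
}

#' Discard spike-inflated energies above a quantile
#'
#' Spike artifacts are short and huge, so they land in the extreme upper
#' tail of the window-energy distribution. Trimming everything above the
#' empirical 0.95 quantile (linear-interpolation definition) bounds their
#' influence on all three quality metrics, including the max that enters
#' the peak-to-average-energy ratio. Values are discarded, not clipped.
#'
#' @param e numeric energy values.
#' @param q trimming quantile in (0, 1), default 0.95.
#' @return the retained energy values (those `<=` the q-quantile).
#' @export
trim_energies <- function(e, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  if (length(e) < 20L)
    stop("need at least 20 energy samples to trim robustly", call. = FALSE)
  cut <- stats::quantile(e, q, names = FALSE, type = 7)
  kept <- e[e <= cut]
  message(sprintf("energy trimming: discarded %d/%d values above %.4g",
                  length(e) - length(kept), length(e), cut))
  kept
}

moment_checks <- function(e, least) {
  e <- as.numeric(e)
  if (length(e) < least)
    stop(sprintf("need at least %d values", least), call. = FALSE)
  sdev <- sqrt(mean((e - mean(e))^2))   # population sd
  if (sdev == 0)
    stop("metric undefined: energy distribution is constant (sd = 0)",
         call. = FALSE)
  list(e = e, m = mean(e), s = sdev)
}

#' Skewness of the energy distribution
#'
#' Standardized third central moment (population, divisor N). Enhancement
#' pushes baseline-noise energies toward zero while leaving contraction
#' energies in place, so a right-skewed energy histogram — larger skewness —
#' signals better contraction/baseline contrast.
#'
#' @param e energy values (typically after [trim_energies()]).
#' @return dimensionless skewness.
#' @export
energy_skewness <- function(e) {
  mc <- moment_checks(e, 3L)
  mean(((mc$e - mc$m) / mc$s)^3)
}

#' Kurtosis of the energy distribution
#'
#' Standardized fourth central moment (population, divisor N; plain, not
#' excess — a Gaussian scores 3). Heavier tails relative to the center mean
#' the baseline mode has collapsed toward zero while contraction energies
#' stand apart.
#'
#' @param e energy values (typically after [trim_energies()]).
#' @return dimensionless kurtosis, >= 1 whenever defined.
#' @export
energy_kurtosis <- function(e) {
  mc <- moment_checks(e, 4L)
  mean(((mc$e - mc$m) / mc$s)^4)
}

#' Peak-to-average-energy ratio (PAER)
#'
#' `10 * log10(max(e)^2 / mean(e)^2)` in dB. Enhancement lowers the mean
#' (baseline suppressed) while the peak contraction energy is largely
#' preserved, so PAER grows with contraction/baseline contrast. Constant
#' energies score 0 dB.
#'
#' @param e energy values (typically after [trim_energies()]).
#' @return PAER in dB.
#' @export
paer <- function(e) {
  e <- as.numeric(e)
  if (length(e) < 1L) stop("empty energies", call. = FALSE)
  if (mean(e) <= 0) stop("PAER undefined: mean energy is not positive",
                         call. = FALSE)
  10 * log10(max(e)^2 / mean(e)^2)
}

#' All three channel-quality metrics for one series
#'
#' Composition `window_energy -> trim_energies -> {skewness, kurtosis, PAER}`
#' over the whole channel without segmentation.
#'
#' @param x numeric series (fast wave or enhanced signal).
#' @param n energy window in samples.
#' @param q trimming quantile; `NA` disables trimming.
#' @return one-row data.frame: `skewness`, `kurtosis`, `paer`, `n_used`.
#' @export
channel_metrics <- function(x, n = 50L, q = 0.95) {
  if (length(unique(as.numeric(x))) == 1L)
    stop("metrics undefined: constant channel (sd = 0 energy distribution)",
         call. = FALSE)
  e <- window_energy(x, n)
  if (!is.na(q)) e <- suppressMessages(trim_energies(e, q))
  data.frame(skewness = energy_skewness(e), kurtosis = energy_kurtosis(e),
             paer = paer(e), n_used = length(e))
}

#' Quality metrics for every channel of a recording
#'
#' @param rec an [ehg_recording()] (fast or enhanced band).
#' @param n,q as in [channel_metrics()].
#' @return data.frame with one row per channel: `channel_id`, `band`,
#'   `skewness`, `kurtosis`, `paer`, `n_used`.
#' @export
recording_metrics <- function(rec, n = 50L, q = 0.95) {
  stopifnot(inherits(rec, "ehg_recording"))
  rows <- lapply(seq_len(n_channels(rec)), function(i)
    cbind(channel_id = rec$channel_ids[i], band = rec$band,
          channel_metrics(rec$data[i, ], n, q)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
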
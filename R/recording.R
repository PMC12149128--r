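#' Multi-channel EHG recording
#'
#' Container for a block of uterine surface-electrode voltage samples. Rows
#' are channels, columns are samples; all values are in millivolts. The
#' `band` tag records which processing stage produced the data: `"raw"`
#' straight off the amplifier, `"slow"` (0.01--0.1 Hz) or `"fast"`
#' (0.34--1 Hz) after band-splitting, or `"enhanced"` after envelope
#' weighting (units mV^2 in that case).
#'
#' @param data numeric matrix, channels x samples (mV).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids character vector of unique channel labels, one per row.
#'   Defaults to `"ch1"`, `"ch2"`, ...
#' @param band one of `"raw"`, `"slow"`, `"fast"`, `"enhanced"`.
#' @param meta optional named list of provenance metadata (e.g. edge-transient
#'   flags set by [bandpass()]).
#'
#' @return An object of class `ehg_recording`.
#' @examples
#' rec <- ehg_recording(matrix(rnorm(20), nrow = 2), fs = 5)
#' n_samples(rec)
#' @export
ehg_recording <- function(data, fs, channel_ids = NULL,
                          band = c("raw", "slow", "fast", "enhanced"),
                          meta = list()) {
  band <- match.arg(band)
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop("length(channel_ids) must equal nrow(data)", call. = FALSE)
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique", call. = FALSE)
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop(sprintf("non-finite samples in channel(s): %s",
                 paste(channel_ids[bad], collapse = ", ")), call. = FALSE)
  rownames(data) <- channel_ids
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 band = band, meta = meta),
            class = "ehg_recording")
}

#' @export
print.ehg_recording <- function(x, ...) {
  cat(sprintf("<ehg_recording> %d channel(s) x %d samples @ %g Hz [%s], %.1f s\n",
              nrow(x$data), ncol(x$data), x$fs, x$band, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
plot.ehg_recording <- function(x, channels = seq_len(min(4L, nrow(x$data))), ...) {
  t <- (seq_len(ncol(x$data)) - 1L) / x$fs
  old <- graphics::par(mfrow = c(length(channels), 1L), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    graphics::plot(t, x$data[ch, ], type = "l", xlab = "time (s)",
                   ylab = x$channel_ids[ch], ...)
  }
  invisible(x)
}

#' Number of samples / channels in a recording
#' @param rec an [ehg_recording()].
#' @return integer count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Extract one channel's samples as a numeric vector
#' @param rec an [ehg_recording()].
#' @param channel channel id (character) or row index.
#' @return numeric vector of samples (mV).
#' @export
channel_series <- function(rec, channel) {
  if (is.character(channel)) {
    i <- match(channel, rec$channel_ids)
    if (is.na(i)) stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  } else i <- as.integer(channel)
  rec$data[i, ]
}

#' Per-sample binary contraction mask
#'
#' A 0/1 series at a stated sampling rate marking which samples fall inside a
#' uterine contraction. Masks are typically derived from a tocodynamometer
#' (TOCO) trace and act as ground truth for detector scoring.
#'
#' @param values numeric/integer vector of 0s and 1s.
#' @param fs sampling rate in Hz.
#' @return An object of class `ehg_mask`.
#' @examples
#' m <- ehg_mask(c(0, 0, 1, 1, 0), fs = 5)
#' sum(m$values)
#' @export
ehg_mask <- function(values, fs) {
  values <- as.integer(values)
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("mask values must all be 0 or 1", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(list(values = values, fs = fs), class = "ehg_mask")
}

#' @export
print.ehg_mask <- function(x, ...) {
  cat(sprintf("<ehg_mask> %d samples @ %g Hz, %d positive (%.1f%%)\n",
              length(x$values), x$fs, sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

#' Electrode layout: channel positions on the body surface
#'
#' Coordinates are in millimetres; the y axis points from anterior to
#' posterior, so projecting "along y" collapses depth and leaves the
#' frontal (x, z) plane used for hull-based signaling-distance analysis.
#'
#' @param channel_id character vector of unique channel labels.
#' @param x,y,z numeric coordinates (mm), one per channel.
#' @return An `ehg_layout`, a data.frame with columns
#'   `channel_id`, `x`, `y`, `z`.
#' @examples
#' lay <- ehg_layout(c("a", "b"), x = c(0, 10), y = c(0, 0), z = c(0, 5))
#' @export
ehg_layout <- function(channel_id, x, y, z) {
  channel_id <- as.character(channel_id)
  if (anyDuplicated(channel_id))
    stop(sprintf("duplicate channel id(s): %s",
                 paste(unique(channel_id[duplicated(channel_id)]), collapse = ", ")),
         call. = FALSE)
  n <- length(channel_id)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("x, y, z must each have one value per channel", call. = FALSE)
  coords <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(coords))) {
    bad <- which(!apply(coords, 1L, function(r) all(is.finite(r))))
    stop(sprintf("non-finite coordinate(s) in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(channel_id = channel_id, x = coords[, "x"],
                    y = coords[, "y"], z = coords[, "z"],
                    stringsAsFactors = FALSE)
  class(out) <- c("ehg_layout", "data.frame")
  out
}

#' @export
print.ehg_layout <- function(x, ...) {
  cat(sprintf("<ehg_layout> %d electrodes (mm; y = anterior -> posterior)\n",
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Look up coordinates for a set of channels
#' @param layout an [ehg_layout()].
#' @param channel_ids channels to look up; all must be present.
#' @return numeric matrix with columns x, y, z and one row per channel.
#' @export
layout_coords <- function(layout, channel_ids) {
  i <- match(as.character(channel_ids), layout$channel_id)
  if (anyNA(i))
    stop(sprintf("channel(s) missing from layout: %s",
                 paste(channel_ids[is.na(i)], collapse = ", ")), call. = FALSE)
  m <- as.matrix(layout[i, c("x", "y", "z")])
  rownames(m) <- as.character(channel_ids)
  m
}
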
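# Delimited recording dialect: line 1 is `# fs=<Hz>`, line 2 the channel
# ids, then one CSV row per sample with channels in columns. Diff-able in
# tests and lossless (full double precision).

#' Read a multi-channel recording
#'
#' @param path file path.
#' @param format `"delimited"` (see Details) or `"edf"` (16-bit European
#'   Data Format, physical dimension mV).
#' @return an [ehg_recording()] tagged `band = "raw"`.
#' @details The delimited dialect is comma-separated with samples in rows
#'   and channels in columns, preceded by a `# fs=<Hz>` line and a channel-id
#'   header line. Non-finite samples are rejected with the offending channel
#'   named.
#' @export
read_recording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "edf") return(read_edf(path))
  con <- file(path, "r"); on.exit(close(con))
  l1 <- readLines(con, n = 1L)
  m <- regmatches(l1, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)\\s*$", l1))[[1]]
  if (length(m) != 2L)
    stop(sprintf("malformed header line (expected '# fs=<Hz>'): %s", l1),
         call. = FALSE)
  fs <- as.numeric(m[2])
  ids <- strsplit(readLines(con, n = 1L), ",", fixed = TRUE)[[1]]
  ids <- trimws(ids)
  if (length(ids) == 0L || any(ids == ""))
    stop("malformed channel-id header", call. = FALSE)
  body <- utils::read.csv(con, header = FALSE, colClasses = "numeric")
  if (ncol(body) != length(ids))
    stop(sprintf("header names %d channels but rows have %d columns",
                 length(ids), ncol(body)), call. = FALSE)
  rec <- ehg_recording(t(as.matrix(body)), fs, ids, band = "raw")
  message(sprintf("read %d channel(s) x %d samples @ %g Hz from %s",
                  n_channels(rec), n_samples(rec), fs, path))
  rec
}

#' Write a recording
#'
#' @param rec an [ehg_recording()].
#' @param path output path.
#' @param format `"delimited"` or `"edf"`. Delimited files round-trip
#'   bit-identically; EDF quantizes to 16 bits.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "ehg_recording"))
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(rec$fs, digits = 17)), con)
  writeLines(paste(rec$channel_ids, collapse = ","), con)
  # full double precision so read(write(x)) is bit-identical
  fmt <- sprintf("%.17g", t(rec$data))
  dim(fmt) <- c(n_samples(rec), n_channels(rec))
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Convert contraction intervals to a per-sample mask
#'
#' Intervals are half-open `[start, end)` in seconds; sample `i` (0-based)
#' covers time `i / fs`. Start times floor and end times ceil to sample
#' indices, conservatively including contraction edges. Overlapping
#' intervals are merged with a warning.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param fs target sampling rate (Hz).
#' @param duration_s total mask duration in seconds (defaults to the latest
#'   interval end).
#' @return an [ehg_mask()] of `ceiling(duration_s * fs)` samples.
#' @examples
#' intervals_to_mask(10, 20, fs = 5, duration_s = 30)  # samples 50..99 set
#' @export
intervals_to_mask <- function(start_s, end_s, fs, duration_s = NULL) {
  if (length(start_s) != length(end_s))
    stop("start_s and end_s lengths differ", call. = FALSE)
  if (any(start_s < 0) || any(end_s < 0))
    stop("negative interval times", call. = FALSE)
  if (any(end_s < start_s))
    stop("interval ends before it starts", call. = FALSE)
  if (is.null(duration_s))
    duration_s <- if (length(end_s)) max(end_s) else 0
  n <- ceiling(duration_s * fs)
  v <- integer(max(n, 0L))
  if (length(start_s)) {
    o <- order(start_s)
    ss <- start_s[o]; ee <- end_s[o]
    if (any(ss[-1] < utils::head(ee, -1)))
      warning("overlapping intervals merged", call. = FALSE)
    for (k in seq_along(ss)) {
      lo <- floor(ss[k] * fs) + 1L
      hi <- min(n, ceiling(ee[k] * fs))
      if (hi >= lo) v[lo:hi] <- 1L
    }
  }
  ehg_mask(v, fs)
}

#' Read a contraction mask
#'
#' Accepts either a per-sample file (header `# fs=<Hz>`, then one 0/1 value
#' per line under a `mask` header) or an interval list (CSV with columns
#' `start_s`, `end_s`). Per-sample masks whose rate differs from
#' `fs_target` are rejected; interval lists are rasterized at `fs_target`
#' via [intervals_to_mask()].
#'
#' @param path file path.
#' @param fs_target sampling rate the mask must score against (Hz).
#' @param duration_s total duration for interval files (seconds).
#' @return an [ehg_mask()] at `fs_target`.
#' @export
read_mask <- function(path, fs_target, duration_s = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  l1 <- readLines(path, n = 1L)
  if (grepl("^#\\s*fs\\s*=", l1)) {
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", l1))
    df <- utils::read.csv(path, skip = 1L)
    if (!("mask" %in% names(df)))
      stop("per-sample mask file needs a 'mask' column", call. = FALSE)
    if (!isTRUE(all.equal(fs, fs_target)))
      stop(sprintf("mask rate %g Hz does not match target %g Hz",
                   fs, fs_target), call. = FALSE)
    return(ehg_mask(df$mask, fs_target))
  }
  df <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop("interval mask file needs columns start_s,end_s", call. = FALSE)
  intervals_to_mask(df$start_s, df$end_s, fs_target, duration_s)
}

#' Write a per-sample mask
#' @param mask an [ehg_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ehg_mask"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", format(mask$fs, digits = 17)), "mask"), con)
  writeLines(as.character(mask$values), con)
  invisible(path)
}

#' Read an electrode layout
#'
#' CSV with columns `channel_id`, `x`, `y`, `z` (mm). Duplicate ids and
#' missing coordinates are rejected, the latter naming the offending row.
#'
#' @param path file path.
#' @return an [ehg_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("layout file needs columns channel_id,x,y,z", call. = FALSE)
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]) |
                 !apply(as.matrix(df[, c("x", "y", "z")]), 1L,
                        function(r) all(is.finite(as.numeric(r)))))
  if (length(bad))
    stop(sprintf("missing/non-finite coordinate in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  ehg_layout(df$channel_id, df$x, df$y, df$z)
}

#' Write an electrode layout
#' @param layout an [ehg_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "ehg_layout"))
  df <- as.data.frame(layout)
  df$x <- format(df$x, digits = 17)
  df$y <- format(df$y, digits = 17)
  df$z <- format(df$z, digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
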
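# Minimal European Data Format (EDF) support: fixed 256-byte ASCII header,
# 256 ASCII bytes per signal, then 16-bit little-endian samples grouped into
# data records. The writer emits a single data record holding the whole
# recording (record duration N/fs); the reader handles any record layout as
# long as every signal shares one sampling rate. Values are stored with
# physical dimension mV and quantized to the int16 range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  nc <- n_channels(rec); ns <- n_samples(rec)
  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))                      # local patient id
  wr(edf_pad("Startdate X X X X", 80))            # local recording id
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (1 + nc), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(1, 8))                               # one data record
  wr(edf_num(ns / rec$fs, 8))                     # record duration (s)
  wr(edf_pad(nc, 4))
  pmin_ <- numeric(nc); pmax_ <- numeric(nc)
  for (i in seq_len(nc)) {
    lo <- min(rec$data[i, ]); hi <- max(rec$data[i, ])
    if (hi == lo) { lo <- lo - 1; hi <- hi + 1 }
    pmin_[i] <- lo; pmax_[i] <- hi
  }
  for (i in seq_len(nc)) wr(edf_pad(rec$channel_ids[i], 16))
  for (i in seq_len(nc)) wr(edf_pad("", 80))      # transducer
  for (i in seq_len(nc)) wr(edf_pad("mV", 8))
  for (i in seq_len(nc)) wr(edf_num(pmin_[i], 8))
  for (i in seq_len(nc)) wr(edf_num(pmax_[i], 8))
  for (i in seq_len(nc)) wr(edf_pad(-32768, 8))
  for (i in seq_len(nc)) wr(edf_pad(32767, 8))
  for (i in seq_len(nc)) wr(edf_pad("", 80))      # prefilter
  for (i in seq_len(nc)) wr(edf_pad(ns, 8))       # samples per record
  for (i in seq_len(nc)) wr(edf_pad("", 32))
  for (i in seq_len(nc)) {
    # re-parse the header's truncated ASCII bounds so scaling round-trips
    lo <- as.numeric(edf_num(pmin_[i], 8)); hi <- as.numeric(edf_num(pmax_[i], 8))
    dig <- round((rec$data[i, ] - lo) / (hi - lo) * 65535 - 32768)
    writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  num <- function(w) {
    s <- trimws(rd(w))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("malformed EDF header field: '%s'", s),
                       call. = FALSE)
    v
  }
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (bad version field)", call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  num(8)                                           # header bytes
  rd(44)
  n_rec <- num(8)
  dur <- num(8)
  nc <- as.integer(num(4))
  labels <- trimws(vapply(seq_len(nc), function(i) rd(16), ""))
  for (i in seq_len(nc)) rd(80)
  dims <- trimws(vapply(seq_len(nc), function(i) rd(8), ""))
  pmin_ <- vapply(seq_len(nc), function(i) num(8), 0)
  pmax_ <- vapply(seq_len(nc), function(i) num(8), 0)
  dmin_ <- vapply(seq_len(nc), function(i) num(8), 0)
  dmax_ <- vapply(seq_len(nc), function(i) num(8), 0)
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(num(8)), 0L)
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported",
         call. = FALSE)
  fs <- spr[1] / dur
  data <- matrix(0, nrow = nc, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) *
        (pmax_[i] - pmin_[i])
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  rec <- ehg_recording(data, fs, labels, band = "raw")
  message(sprintf("read %d channel(s) x %d samples @ %g Hz from %s (%s)",
                  nc, ncol(data), fs, path,
                  paste(unique(dims), collapse = ",")))
  rec
}
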
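# Minimal EDF (European Data Format, 16-bit) writer and reader.
#
# Only the subset needed to round-trip continuous multichannel EEG is
# implemented: one data record spanning the whole recording, per-channel
# physical scaling, no annotations. Values survive the round trip within
# the 16-bit quantization step implied by each channel's physical range.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' @param rec a [recording()]; the sampling rate must be a positive integer.
#' @param path output file.
#' @export
write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data); n <- ncol(rec$data)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(rec$subject_id, 80), pad_field("eegfuse", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(1, 8), pad_field(format(n / rec$sampling_rate, digits = 7), 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_names, pad_field, "", width = 16),
    rep(pad_field("", 80), ns), rep(pad_field("uV", 8), ns),
    vapply(pmin_, function(v) pad_field(format(v, digits = 7), 8), ""),
    vapply(pmax_, function(v) pad_field(format(v, digits = 7), 8), ""),
    rep(pad_field(-32768, 8), ns), rep(pad_field(32767, 8), ns),
    rep(pad_field("", 80), ns), rep(pad_field(n, 8), ns),
    rep(pad_field("", 32), ns))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < w)
      stop("I/O error: truncated EDF header in ", path, call. = FALSE)
    trimws(raw)
  }
  rd(8); sid <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (!is.finite(n_rec) || !is.finite(ns) || ns < 1)
    stop("I/O error: malformed EDF header in ", path, call. = FALSE)
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16); rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80); spr <- as.integer(rdn(8)); rdn(32)
  expected <- 256 * (1 + ns) + 2 * n_rec * sum(spr)
  if (sz < expected) stop("I/O error: truncated EDF data in ", path, call. = FALSE)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) for (i in seq_len(ns)) {
    dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
    phys <- pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
    data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
  }
  recording(data, sampling_rate = spr[1] / dur, channel_names = labels,
            subject_id = sid)
}
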
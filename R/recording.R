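# The Recording container: one subject's multichannel EEG.

#' Construct a Recording
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param subject_id opaque identifier.
#' @param group_label class name (or NA).
#' @return An object of class `recording`.
#' @export
recording <- function(data, sampling_rate, channel_names = rownames(data),
                      subject_id = "s1", group_label = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) abort_invalid("data must be a numeric matrix")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    abort_invalid("channel_names length must equal the channel (row) count")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort_invalid("sampling_rate must be > 0")
  if (any(!is.finite(data))) abort_invalid("data must be finite")
  rownames(data) <- channel_names
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_names = channel_names, subject_id = subject_id,
                 group_label = group_label), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s [%s]: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group_label, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}

#' Write a recording as a delimited matrix
#'
#' Channels as rows, first column the channel name; a `# sampling_rate:`
#' header line carries the rate.
#'
#' @param rec a [recording()].
#' @param path output file.
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %g", rec$sampling_rate), con)
  writeLines(sprintf("# subject_id: %s", rec$subject_id), con)
  df <- data.frame(channel = rec$channel_names,
                   format(rec$data, digits = 10, trim = TRUE, scientific = FALSE))
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

read_recording_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  rate <- as.numeric(sub(".*sampling_rate:\\s*", "", grep("sampling_rate", hdr, value = TRUE)[1]))
  sid <- sub(".*subject_id:\\s*", "", grep("subject_id", hdr, value = TRUE)[1])
  if (is.na(sid) || length(sid) == 0) sid <- basename(path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (length(unique(nfield)) != 1)
    stop("format error: inconsistent row lengths in ", path, call. = FALSE)
  ch <- vapply(parts, `[[`, "", 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(nfield[1] - 1L)))
  if (any(!is.finite(vals))) stop("format error: non-numeric values in ", path, call. = FALSE)
  if (!is.finite(rate)) stop("format error: missing sampling_rate header in ", path, call. = FALSE)
  recording(vals, sampling_rate = rate, channel_names = ch, subject_id = sid)
}

#' Read a recording from EDF or delimited matrix
#'
#' @param path input file.
#' @param format_hint `"auto"`, `"edf"` or `"tsv"`.
#' @param group_label optional class label to attach.
#' @return A [recording()].
#' @export
read_recording <- function(path, format_hint = c("auto", "edf", "tsv"),
                           group_label = NA_character_) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  fmt <- format_hint
  if (fmt == "auto")
    fmt <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  rec <- if (fmt == "edf") read_recording_edf(path) else read_recording_tsv(path)
  rec$group_label <- group_label
  rec
}

#' Band-pass + notch filter and resample a recording
#'
#' Zero-phase (forward-backward) IIR filtering: 2nd-order Butterworth
#' high-pass at `band_low`, 4th-order Butterworth low-pass at `band_high`,
#' and a 2nd-order Butterworth band-stop of ±2 Hz around `notch`; then
#' polyphase resampling to `target_rate`. Defaults follow the conventional
#' resting-state pipeline: 0.1-40 Hz passband, 50 Hz mains notch, 250 Hz.
#'
#' @param rec a [recording()].
#' @param band_low high-pass edge, Hz.
#' @param band_high low-pass edge, Hz.
#' @param notch mains frequency, Hz (NA to skip).
#' @param target_rate output sampling rate, Hz.
#' @return The filtered, resampled [recording()].
#' @export
filter_resample <- function(rec, band_low = 0.1, band_high = 40, notch = 50,
                            target_rate = 250) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (!(band_low >= 0 && band_low < band_high)) abort_invalid("need 0 <= band_low < band_high")
  if (band_high >= nyq) abort_invalid("band_high must be below the Nyquist frequency")
  if (target_rate > rec$sampling_rate) abort_invalid("target_rate must not exceed the input rate")
  hp <- if (band_low > 0) signal::butter(2, band_low / nyq, type = "high") else NULL
  lp <- signal::butter(4, band_high / nyq, type = "low")
  bs <- if (!is.na(notch) && notch < nyq)
    signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop") else NULL
  filt1 <- function(x) {
    if (!is.null(hp)) x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    if (!is.null(bs)) x <- signal::filtfilt(bs, x)
    x
  }
  out <- t(apply(rec$data, 1, filt1))
  if (target_rate != rec$sampling_rate) {
    fr <- ratio_approx(target_rate / rec$sampling_rate)
    out <- t(apply(out, 1, function(x) signal::resample(x, fr[1], fr[2])))
  }
  recording(out, sampling_rate = target_rate, channel_names = rec$channel_names,
            subject_id = rec$subject_id, group_label = rec$group_label)
}

# small-denominator rational approximation for the resampling ratio
ratio_approx <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  abort_invalid("resampling ratio is not a simple rational number")
}

#' Re-reference to bilateral mastoids and drop the mastoid channels
#'
#' Subtracts the mean of the two mastoid signals from every channel, then
#' removes the mastoid channels (19-channel input yields 17). If neither
#' mastoid is present the recording is passed through unchanged with a
#' notice, so purely synthetic 17-channel data flows through the same
#' pipeline.
#'
#' @param rec a [recording()].
#' @param mastoid_channels pair of channel names (default `c("M1","M2")`).
#' @return The re-referenced [recording()]; attribute `reference` stores the
#'   subtracted signal so the operation can be inverted.
#' @export
rereference_select <- function(rec, mastoid_channels = c("M1", "M2")) {
  stopifnot(inherits(rec, "recording"))
  present <- mastoid_channels %in% rec$channel_names
  if (!any(present)) {
    notice("no mastoid channels (%s) found; pass-through",
           paste(mastoid_channels, collapse = ","))
    return(rec)
  }
  if (!all(present)) abort_invalid("one mastoid channel is missing")
  mi <- match(mastoid_channels, rec$channel_names)
  ref <- colMeans(rec$data[mi, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$data)), mi)
  out <- rec$data[keep, , drop = FALSE] - rep(ref, each = length(keep))
  res <- recording(out, sampling_rate = rec$sampling_rate,
                   channel_names = rec$channel_names[keep],
                   subject_id = rec$subject_id, group_label = rec$group_label)
  attr(res, "reference") <- ref
  res
}
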
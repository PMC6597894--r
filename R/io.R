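# File I/O: WAV (PCM 16-bit mono), signal CSV, event/interval CSV round trips.
# The WAV codec is a minimal RIFF reader/writer for the one profile the
# recordings use (16-bit PCM, single channel); anything else is refused.

#' Read a waveform from WAV or CSV
#'
#' WAV files must be 16-bit PCM mono; samples are decoded to \[-1, 1) and the
#' sampling rate is taken from the header. CSV files may either have columns
#' `time_s,value` (the rate is inferred from the median time step, which must
#' be uniform to within 1%) or a single column of samples, in which case `fs`
#' must be supplied.
#'
#' @param path Path to the file.
#' @param format `"wav"` or `"csv"`; the default guesses from the extension.
#' @param fs Sampling rate in Hz, required for single-column CSV input.
#' @param label Provenance label stored on the record.
#' @return A [signal_record()].
#' @export
read_signal <- function(path, format = c("auto", "wav", "csv"), fs = NULL,
                        label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") read_wav(path, label = label)
  else read_signal_csv(path, fs = fs, label = label)
}

#' @rdname read_signal
#' @export
read_wav <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; fmt_code <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", size)
      fmt_code <- sum(as.integer(fmt[1:2]) * c(1L, 256L))
      channels <- sum(as.integer(fmt[3:4]) * c(1L, 256L))
      fs <- sum(as.integer(fmt[5:8]) * 256^(0:3))
      bits <- sum(as.integer(fmt[15:16]) * c(1L, 256L))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (channels != 1L) stop("mono required: file has ", channels,
                               " channels")
      if (fmt_code != 1L || bits != 16L)
        stop("only 16-bit PCM WAV is supported")
      samples <- readBin(con, "integer", size %/% 2L, 2L, signed = TRUE,
                         endian = "little")
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  signal_record(samples / 32768, fs, label = label)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are clipped to \[-1, 1 - 2^-15\] and quantized to 16 bits.
#'
#' @param x A [signal_record()] or numeric vector.
#' @param path Output path.
#' @param fs Sampling rate, required when `x` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL) {
  x <- as_signal_record(x, fs)
  q <- as.integer(pmax(-32768, pmin(32767, round(x$samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                 # PCM
  writeBin(1L, con, 2L, endian = "little")                 # mono
  writeBin(as.integer(round(x$fs)), con, 4L, endian = "little")
  writeBin(as.integer(round(x$fs)) * 2L, con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")                 # block align
  writeBin(16L, con, 2L, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(q, con, 2L, endian = "little")
  invisible(path)
}

read_signal_csv <- function(path, fs = NULL, label = basename(path)) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) >= 2L) {
    tm <- as.numeric(df[[1L]]); val <- as.numeric(df[[2L]])
    dt <- diff(tm)
    med <- stats::median(dt)
    if (med <= 0 || any(abs(dt - med) > 0.01 * med))
      stop("non-uniform time column in CSV (must be uniform within 1%)")
    signal_record(val, 1 / med, label = label, t0 = tm[1L])
  } else {
    if (is.null(fs)) stop("fs must be supplied for single-column CSV input")
    signal_record(as.numeric(df[[1L]]), fs, label = label)
  }
}

#' Write a signal as a `time_s,value` CSV
#'
#' @param x A [signal_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(is_signal_record(x))
  df <- data.frame(time_s = signal_times(x), value = x$samples)
  utils::write.csv(fmt_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Format numeric columns at full double precision so CSV round trips are
# bit-exact; reporting-level rounding happens only in print methods.
fmt_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], digits = 17, format = "g"))
  df
}

#' Write and read per-beat valve event tables
#'
#' Columns: `beat_index, anchor_time_s, rr_ms, t_mc_ms, t_ao_ms, t_ac_ms,
#' t_mo_ms`; an empty cell marks a missing event. Times are stored at full
#' precision so a round trip reproduces in-memory values exactly.
#'
#' @param events A data frame of events (as returned by
#'   [run_event_pipeline()] in its `$events` element).
#' @param path File path.
#' @return `path` (writer, invisibly) or the events data frame (reader).
#' @export
write_events_csv <- function(events, path) {
  cols <- c("beat_index", "anchor_time_s", "rr_ms",
            "t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")
  stopifnot(all(cols %in% names(events)))
  utils::write.csv(fmt_num_df(events[cols]), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write and read per-beat interval tables
#'
#' Columns: `beat_index, rr_ms, ict_ms, vet_ms, irt_ms, pep_ms, sti_ms`
#' (plus `subject_id` and `group` when present); empty cell = missing.
#'
#' @param intervals A `beat_intervals` data frame from [compute_intervals()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the intervals data frame (reader).
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(fmt_num_df(as.data.frame(intervals)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  df <- utils::read.csv(path)
  num <- setdiff(names(df), c("subject_id", "group"))
  for (j in num) df[[j]] <- as.numeric(df[[j]])
  class(df) <- c("beat_intervals", "data.frame")
  df
}

#' Read an R-peak annotation file
#'
#' A single-column CSV of R-peak times in seconds (header `r_time_s`
#' optional), used as an external timing reference for ECG-reference mode.
#'
#' @param path File path.
#' @return Numeric vector of strictly increasing times in seconds.
#' @export
read_rpeaks_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, header = grepl("[A-Za-z]", first))
  tt <- as.numeric(df[[1L]])
  if (any(diff(tt) <= 0)) stop("R-peak times must be strictly increasing")
  tt
}
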
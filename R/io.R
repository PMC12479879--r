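# Recording / event / waveform containers and their readers and writers.
#
# A recording holds calibrated voltages (volts) for two electrode channels at a
# fixed sampling rate. On-disk containers are deliberately simple and open:
# RIFF/WAV (float32 preferred, PCM16 accepted) or raw float32 interleaved
# samples with a JSON sidecar carrying the sampling rate and volt scale.

#' Construct a two-channel recording
#'
#' @param samples numeric matrix, N samples x 2 channels, in volts.
#' @param fs sampling rate in Hz.
#' @param meta optional named list of free-form metadata (tank, date, fish ids).
#'
#' @return An object of class `eod_recording`: a list with elements `samples`
#'   (N x 2 matrix), `fs`, `duration_s` and `meta`.
#' @export
eod_recording <- function(samples, fs, meta = list()) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2L)
    stop("recording must have exactly 2 channels, got ", ncol(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(samples)))
    stop("recording contains non-finite sample values")
  structure(
    list(samples = samples, fs = fs,
         duration_s = nrow(samples) / fs, meta = meta),
    class = "eod_recording")
}

#' @export
print.eod_recording <- function(x, ...) {
  cat(sprintf("<eod_recording> 2 channels, %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), x$fs, x$duration_s))
  rng <- range(x$samples)
  cat(sprintf("  voltage range [%.4g, %.4g] V\n", rng[1], rng[2]))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

## ---- minimal RIFF/WAV support (float32 and PCM16) ----

wav_write_chunk <- function(con, id, payload) {
  writeChar(id, con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
}

#' Write a multichannel WAV file
#'
#' Writes a standard RIFF/WAV file, either IEEE float32 (format 3, the
#' default: millivolt-scale signals survive without quantization) or 16-bit
#' PCM (format 1). For PCM the samples must already lie in \[-1, 1\].
#'
#' @param audio numeric vector or N x C matrix of samples.
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @param format `"float32"` or `"pcm16"`.
#' @param allow_clip for PCM, clip out-of-range samples instead of erroring.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, fs, format = c("float32", "pcm16"),
                      allow_clip = FALSE) {
  format <- match.arg(format)
  audio <- as.matrix(audio)
  n <- nrow(audio); nch <- ncol(audio)
  interleaved <- as.numeric(t(audio))
  clipping <- length(interleaved) && max(abs(interleaved)) > 1
  if (clipping && !allow_clip)
    stop("samples outside [-1, 1]; set allow_clip = TRUE to clip")
  if (format == "pcm16") {
    if (clipping) interleaved <- pmin(1, pmax(-1, interleaved))
    payload <- writeBin(as.integer(round(interleaved * 32767)), raw(),
                        size = 2, endian = "little")
    bits <- 16L; fmt <- 1L
  } else {
    payload <- writeBin(interleaved, raw(), size = 4, endian = "little")
    bits <- 32L; fmt <- 3L
  }
  block_align <- nch * bits / 8L
  fmt_payload <- c(
    writeBin(c(fmt, nch), raw(), size = 2, endian = "little"),
    writeBin(as.integer(c(fs, fs * block_align)), raw(), size = 4, endian = "little"),
    writeBin(as.integer(c(block_align, bits)), raw(), size = 2, endian = "little"))
  fact_payload <- writeBin(as.integer(n), raw(), size = 4, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  body_len <- 4L + (8L + length(fmt_payload)) + (8L + length(payload)) +
    if (fmt == 3L) 8L + length(fact_payload) else 0L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(body_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  wav_write_chunk(con, "fmt ", fmt_payload)
  if (fmt == 3L) wav_write_chunk(con, "fact", fact_payload)
  wav_write_chunk(con, "data", payload)
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (N x C matrix), `fs`, `bits`, `format`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0) break
    chunk <- readBin(con, "raw", len)
    if (len %% 2L == 1L) readBin(con, "raw", 1)  # chunks are word-aligned
    if (id == "fmt ") fmt <- chunk
    if (id == "data") data_raw <- chunk
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  audio_fmt <- readBin(fmt[1:2], "integer", 1, size = 2, endian = "little")
  nch <- readBin(fmt[3:4], "integer", 1, size = 2, endian = "little")
  fs <- readBin(fmt[5:8], "integer", 1, size = 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, size = 2, endian = "little")
  if (audio_fmt == 3L && bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else if (audio_fmt == 1L && bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32767
  } else {
    stop("unsupported WAV encoding (format ", audio_fmt, ", ", bits, " bits)")
  }
  list(samples = matrix(x, ncol = nch, byrow = TRUE), fs = fs,
       bits = bits, format = if (audio_fmt == 3L) "float32" else "pcm16")
}

## ---- recording containers ----

#' Read a two-channel recording
#'
#' Supported containers: RIFF/WAV (`format = "wav"`; float32 or PCM16, the
#' sampling rate comes from the header) and raw float32 channel-interleaved
#' samples with a JSON sidecar `<path>.json` holding `fs`, `n_channels` and
#' `volt_scale` (`format = "raw"`). Voltages are restored to volts using the
#' stored scale factor.
#'
#' @param path file path.
#' @param format `"wav"` or `"raw"`.
#' @param meta optional metadata list attached to the recording.
#' @return An [eod_recording()].
#' @export
read_recording <- function(path, format = c("wav", "raw"), meta = list()) {
  format <- match.arg(format)
  if (format == "wav") {
    w <- read_wav(path)
    if (ncol(w$samples) != 2L)
      stop("expected a 2-channel recording, got ", ncol(w$samples), " channel(s)")
    return(eod_recording(w$samples, w$fs, meta))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "volt_scale"))
    if (is.null(info[[f]])) stop("sidecar is missing field '", f, "'")
  if (info$n_channels != 2L)
    stop("expected a 2-channel recording, got ", info$n_channels, " channel(s)")
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "numeric", file.info(path)$size / 4, size = 4,
               endian = "little")
  eod_recording(matrix(x * info$volt_scale, ncol = 2L, byrow = TRUE),
                info$fs, meta)
}

#' Write a two-channel recording
#'
#' @param recording an [eod_recording()].
#' @param path output path.
#' @param format `"wav"` (float32) or `"raw"` (float32 interleaved + JSON
#'   sidecar).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("wav", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "eod_recording"))
  if (format == "wav") {
    # float32 stores voltages verbatim; the [-1, 1] audio range check does
    # not apply to calibrated volts
    write_wav(recording$samples, path, recording$fs, format = "float32",
              allow_clip = TRUE)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(t(recording$samples)), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(
      list(fs = recording$fs, n_channels = 2L, volt_scale = 1.0,
           n_samples = nrow(recording$samples)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

## ---- event tables ----

eod_event_cols <- c("t_s", "channel", "peak_amp_V", "label", "truth")

#' Assemble an EOD event table
#'
#' @param t_s event times in seconds (at the absolute-maximum sample).
#' @param channel channel index (0 or 1) with the larger amplitude.
#' @param peak_amp_V signed voltage at the extremum.
#' @param label optional cluster/fish identity.
#' @param truth optional ground-truth identity (synthetic data).
#' @param ... further per-event columns (e.g. `collision`).
#' @return data.frame sorted by `t_s` with the canonical columns.
#' @export
eod_events <- function(t_s, channel, peak_amp_V,
                       label = NA_character_, truth = NA_character_, ...) {
  n <- length(t_s)
  df <- data.frame(t_s = as.numeric(t_s),
                   channel = rep_len(as.integer(channel), n),
                   peak_amp_V = rep_len(as.numeric(peak_amp_V), n),
                   label = rep_len(as.character(label), n),
                   truth = rep_len(as.character(truth), n),
                   ..., stringsAsFactors = FALSE)
  df[order(df$t_s), , drop = FALSE]
}

#' Write/read EOD event tables as CSV
#'
#' The CSV carries the canonical header `t_s,channel,peak_amp_V,label,truth`
#' (plus any extra columns present, e.g. the simulator's `collision` flag) and
#' round-trips field-for-field.
#'
#' @param events data.frame with the canonical event columns, sorted by `t_s`.
#' @param path CSV path.
#' @return `path` invisibly (write); the event data.frame (read).
#' @export
write_events_csv <- function(events, path) {
  missing_cols <- setdiff(eod_event_cols, names(events))
  if (length(missing_cols))
    stop("events table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.unsorted(events$t_s))
    stop("events must be sorted by t_s")
  extra <- setdiff(names(events), eod_event_cols)
  write.csv(events[, c(eod_event_cols, extra), drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(t_s = "character"))
  missing_cols <- setdiff(eod_event_cols, names(df))
  if (length(missing_cols))
    stop("event CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  t_s <- suppressWarnings(as.numeric(df$t_s))
  if (nrow(df) && anyNA(t_s))
    stop("non-numeric t_s value(s) in ", path)
  df$t_s <- t_s
  df$channel <- as.integer(df$channel)
  df$peak_amp_V <- as.numeric(df$peak_amp_V)
  df$label <- as.character(df$label)
  df$truth <- as.character(df$truth)
  if ("collision" %in% names(df)) df$collision <- as.logical(df$collision)
  df
}

## ---- waveform containers ----

#' Write/read extracted waveforms
#'
#' Waveforms are stored as an n x L numeric CSV (`<base>.waveforms.csv`), a
#' parallel event table (`<base>.events.csv`) and a JSON metadata file
#' (`<base>.json` with `n`, `n_samples`, `fs`). The round trip is lossless to
#' full double precision.
#'
#' @param waveforms n x L matrix of normalized waveforms (rows in \[-1, 1\]),
#'   with the parallel event table in `attr(waveforms, "events")`.
#' @param base base path (no extension).
#' @param fs sampling rate the waveforms were extracted at.
#' @return `base` invisibly (write); the waveform matrix with its `events`
#'   attribute (read).
#' @export
write_waveforms <- function(waveforms, base, fs = attr(waveforms, "fs")) {
  if (is.list(waveforms) && !is.data.frame(waveforms)) {
    lens <- lengths(waveforms)
    if (length(unique(lens)) > 1)
      stop("ragged waveform lengths: ", paste(unique(lens), collapse = ", "))
    ev <- attr(waveforms, "events")
    waveforms <- do.call(rbind, waveforms)
    attr(waveforms, "events") <- ev
  }
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) > 0 && !all(is.finite(waveforms)))
    stop("waveforms contain non-finite values")
  events <- attr(waveforms, "events")
  if (is.null(events))
    events <- eod_events(numeric(0), integer(0), numeric(0),
                         character(0), character(0))
  if (nrow(events) != nrow(waveforms))
    stop("event table length does not match waveform count")
  utils::write.table(format(waveforms, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(base, ".waveforms.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  write_events_csv(events, paste0(base, ".events.csv"))
  jsonlite::write_json(list(n = nrow(waveforms), n_samples = ncol(waveforms),
                            fs = if (is.null(fs)) NA else fs),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(base) {
  meta_path <- paste0(base, ".json")
  if (!file.exists(meta_path)) stop("missing waveform metadata: ", meta_path)
  info <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (info$n == 0) {
    wf <- matrix(numeric(0), nrow = 0, ncol = info$n_samples)
  } else {
    wf <- as.matrix(read.csv(paste0(base, ".waveforms.csv"), header = FALSE))
    dimnames(wf) <- NULL
    if (ncol(wf) != info$n_samples || nrow(wf) != info$n)
      stop("waveform matrix shape does not match metadata")
  }
  attr(wf, "events") <- read_events_csv(paste0(base, ".events.csv"))
  if (!is.null(info$fs) && !is.na(info$fs)) attr(wf, "fs") <- info$fs
  wf
}
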
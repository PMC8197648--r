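# Minimal mono WAV I/O (PCM16 and IEEE float32). Covers reading speech
# recordings in and writing stimulation waveforms out; no installed R
# package in this stack provides WAV support.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit mono files.
#' Multi-channel files are averaged to mono.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal()] with samples in `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else {
    stop(sprintf("unsupported WAV format (format %d, %d bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_signal(x, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param x an [audio_signal()], [stimulus_waveform()] or numeric vector.
#' @param path output path.
#' @param rate sampling rate (taken from `x` when it is a signal object).
#' @param bits 16 (PCM, values clipped to `[-1, 1]`) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate = NULL, bits = 16) {
  if (inherits(x, "audio_signal")) { v <- x$samples; rate <- x$rate }
  else if (inherits(x, c("stimulus_waveform", "normalized_waveform",
                         "envelope_signal", "theta_envelope"))) {
    v <- x$values; rate <- x$rate
  } else {
    check_finite_numeric(x, "x"); v <- as.numeric(x)
    if (is.null(rate)) stop("`rate` required for bare numeric input",
                            call. = FALSE)
  }
  stopifnot(bits %in% c(16, 32))
  bytes <- bits / 8
  data_size <- length(v) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmin(pmax(round(v * 32768), -32768), 32767)), con,
             2, endian = "little")
  } else {
    writeBin(v, con, 4, endian = "little")
  }
  invisible(path)
}

#' Write a stimulation waveform as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `time_s` and `current_mA`; the sidecar
#' (`<path>.json`) records source, phase, band and maximum current.
#'
#' @param wave a [stimulus_waveform()].
#' @param path output CSV path.
#' @param band theta band recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(wave, path, band = c(4, 8)) {
  stopifnot(inherits(wave, "stimulus_waveform"))
  df <- data.frame(time_s = (seq_along(wave$values) - 1) / wave$rate,
                   current_mA = wave$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(source = wave$source, phase_deg = wave$phase_deg,
               band_hz = band, max_current_mA = wave$max_current,
               rate_hz = wave$rate, n_samples = length(wave$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
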
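#' One roost-night of audio
#'
#' Container for the waveform of a single roost-night together with its
#' sampling rate and identifying metadata. Samples are real-valued on a
#' nominal full scale of \[-1, 1\].
#'
#' @param samples Numeric vector of audio samples; must be finite.
#' @param sample_rate Sampling rate in Hz; must be positive.
#' @param start_clock Time of day at which the recording starts, as
#'   `"HH:MM"` or `"HH:MM:SS"`. Recordings nominally run 16:00 to 08:00.
#' @param site Site identifier.
#' @param date Recording date (anything coercible by [as.Date()]).
#' @return An object of class `audio_night`.
#' @examples
#' an <- audio_night(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' an
#' @export
audio_night <- function(samples, sample_rate, start_clock = "16:00",
                        site = "site1", date = Sys.Date()) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         start_clock = start_clock, site = site, date = as.Date(date)),
    class = "audio_night"
  )
}

#' @method print audio_night
#' @export
print.audio_night <- function(x, ...) {
  cat(sprintf("<audio_night> %s %s: %.1f s at %g Hz (start %s)\n",
              x$site, format(x$date), length(x$samples) / x$sample_rate,
              x$sample_rate, x$start_clock))
  invisible(x)
}

#' @export
length.audio_night <- function(x) length(x$samples)

audio_duration_s <- function(audio) length(audio$samples) / audio$sample_rate

parse_clock_s <- function(clock) {
  parts <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || anyNA(parts)) stop("clock must be 'HH:MM' or 'HH:MM:SS'")
  parts <- c(parts, 0, 0)[1:3]
  parts[1] * 3600 + parts[2] * 60 + parts[3]
}

# Seconds from the recording start to the next occurrence of clock time
# `clock`; wraps past midnight for overnight recordings.
clock_offset_s <- function(audio, clock) {
  d <- parse_clock_s(clock) - parse_clock_s(audio$start_clock)
  if (d < 0) d <- d + 86400
  d
}

# Extract [t_start_s, t_end_s) as a new audio_night. Errors if the window
# falls outside the recording.
audio_window <- function(audio, t_start_s, t_end_s) {
  n <- length(audio$samples)
  i0 <- floor(t_start_s * audio$sample_rate) + 1L
  i1 <- floor(t_end_s * audio$sample_rate)
  if (t_start_s < 0 || i1 > n || t_end_s <= t_start_s)
    stop(sprintf("window [%g, %g] s outside recording of %.1f s",
                 t_start_s, t_end_s, n / audio$sample_rate))
  audio_night(audio$samples[i0:i1], audio$sample_rate,
              start_clock = audio$start_clock, site = audio$site,
              date = audio$date)
}

#' Read a PCM WAV file as an `audio_night`
#'
#' Reads uncompressed RIFF/WAVE audio (8-, 16- or 24-bit integer PCM).
#' Stereo or multi-channel files are downmixed by averaging channels.
#' Samples are rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @inheritParams audio_night
#' @return An [audio_night()] object.
#' @export
read_wav <- function(path, start_clock = "16:00", site = "site1",
                     date = Sys.Date()) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  if (fmt$format != 1L) stop("only integer PCM WAV is supported")
  x <- switch(
    as.character(fmt$bits),
    "8" = (as.numeric(as.integer(data_raw)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer",
                              n = length(data_raw) / 2, size = 2,
                              signed = TRUE, endian = "little")) / 32768,
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    stop("unsupported PCM bit depth: ", fmt$bits)
  )
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_night(x, fmt$sample_rate, start_clock = start_clock, site = site,
              date = date)
}

#' Write an `audio_night` as 16-bit PCM WAV
#'
#' @param audio An [audio_night()] object. Samples outside \[-1, 1\] are
#'   clipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_night"))
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(audio$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
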
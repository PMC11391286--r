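#' Per-second band-limited PSD series
#'
#' Container for a per-second calling-intensity series: one value per second
#' of audio, either band-integrated power in dB or, after
#' [normalize_night()], a unit-scale normalized series (nPSD).
#'
#' @param values Numeric vector, one value per second.
#' @param t0_s Time (s, from recording start) of the first value.
#' @param band_hz Length-2 numeric, the integration band in Hz.
#' @param normalized Logical: is this a unit-scale normalized series?
#' @return An object of class `psd_series`.
#' @export
psd_series <- function(values, t0_s = 0, band_hz = c(1000, 3000),
                       normalized = FALSE) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("PSD values must be finite")
  structure(
    list(values = values, t0_s = as.numeric(t0_s),
         band_hz = as.numeric(band_hz), normalized = isTRUE(normalized)),
    class = "psd_series"
  )
}

#' @method print psd_series
#' @export
print.psd_series <- function(x, ...) {
  cat(sprintf("<psd_series> %d s from t=%g s, band %g-%g Hz%s\n",
              length(x$values), x$t0_s, x$band_hz[1], x$band_hz[2],
              if (x$normalized) " (normalized)" else " (dB)"))
  invisible(x)
}

#' @export
length.psd_series <- function(x) length(x$values)

#' @export
plot.psd_series <- function(x, ...) {
  plot(x$t0_s + seq_along(x$values) - 1, x$values, type = "l",
       xlab = "time (s)",
       ylab = if (x$normalized) "nPSD" else "band power (dB)", ...)
  invisible(x)
}

# periodic Hann window (COLA-exact at 50% overlap)
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided Welch PSD of a single frame: segments of `nfft` samples with 50%
# overlap, periodic Hann taper, periodogram normalised so that
# sum(psd) * (fs / nfft) ~ var(x) for white noise.
welch_psd <- function(x, fs, nfft = 256) {
  n <- length(x)
  if (n < nfft) nfft <- 2^floor(log2(n))
  hop <- nfft %/% 2
  w <- hann_window(nfft)
  norm <- fs * sum(w^2)
  starts <- seq(1L, n - nfft + 1L, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    X <- stats::fft(seg)
    p <- (Mod(X[1:(nfft %/% 2 + 1)])^2) / norm
    p[2:(nfft %/% 2)] <- 2 * p[2:(nfft %/% 2)] # one-sided
    acc <- acc + p
  }
  list(psd = acc / length(starts), freq = (0:(nfft %/% 2)) * fs / nfft,
       df = fs / nfft)
}

band_power_from_psd <- function(psd, band) {
  keep <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[keep]) * psd$df
}

# Vectorised per-second Welch band power: all Welch segments of a run of
# whole-second frames go through one mvfft call, chunked to bound memory.
band_power_per_second <- function(x, fs, band, nfft = 256,
                                  chunk_s = 256L) {
  frame_len <- as.integer(round(fs))
  n_sec <- floor(length(x) / frame_len)
  hop <- nfft %/% 2
  w <- hann_window(nfft)
  norm <- fs * sum(w^2)
  seg_starts <- seq(1L, frame_len - nfft + 1L, by = hop)
  n_seg <- length(seg_starts)
  freq <- (0:(nfft %/% 2)) * fs / nfft
  keep <- which(freq >= band[1] & freq <= band[2])
  side <- rep(2, nfft %/% 2 + 1)
  side[c(1, nfft %/% 2 + 1)] <- 1 # DC and Nyquist are not doubled
  wt <- side[keep] / (norm * n_seg) * (fs / nfft) # fold df into the weight
  out <- numeric(n_sec)
  rel_idx <- outer(0:(nfft - 1L), seg_starts, "+") # nfft x n_seg
  for (c0 in seq(1L, n_sec, by = chunk_s)) {
    secs <- c0:min(n_sec, c0 + chunk_s - 1L)
    idx <- outer(as.vector(rel_idx), (secs - 1L) * frame_len, "+")
    m <- matrix(x[idx], nrow = nfft) * w
    P <- Mod(stats::mvfft(m)[keep, , drop = FALSE])^2
    bp <- colSums(wt * P)
    out[secs] <- colSums(matrix(bp, nrow = n_seg))
  }
  out
}

DB_FLOOR <- -120

power_to_db <- function(p) {
  pmax(10 * log10(pmax(p, 10^(DB_FLOOR / 10))), DB_FLOOR)
}

#' Per-second band-integrated power spectral density
#'
#' Splits the recording into non-overlapping 1 s frames aligned to the
#' recording start (a partial trailing frame is dropped), estimates the PSD
#' within each frame by Welch's method (Hann windows, 50% overlap), integrates
#' it over `band`, and reports the result in dB (`10*log10`, floored at
#' -120 dB for zero power).
#'
#' @param audio An [audio_night()].
#' @param band Length-2 numeric, integration band in Hz; must lie within
#'   \[0, sample_rate / 2\].
#' @param nfft Welch segment length in samples.
#' @return A [psd_series()] in dB, one value per whole second of audio.
#' @examples
#' fs <- 8000
#' tone <- audio_night(sin(2 * pi * 2000 * seq_len(2 * fs) / fs), fs)
#' band_psd_series(tone, c(1000, 3000))
#' @export
band_psd_series <- function(audio, band = c(1000, 3000), nfft = 256) {
  stopifnot(inherits(audio, "audio_night"))
  fs <- audio$sample_rate
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop("band must lie within [0, sample_rate/2]")
  n_sec <- floor(length(audio$samples) / fs)
  if (n_sec < 1) stop("audio shorter than 1 s")
  vals <- band_power_per_second(audio$samples, fs, band, nfft)
  psd_series(power_to_db(vals), t0_s = 0, band_hz = band, normalized = FALSE)
}

#' Write / read a PSD series as CSV
#'
#' Two columns (`time_s`, `value`); metadata (band, t0, normalized flag) in
#' `#`-prefixed header lines.
#'
#' @param psd A [psd_series()].
#' @param path File path.
#' @return `write_psd_csv()` returns `path` invisibly; `read_psd_csv()`
#'   returns a [psd_series()].
#' @export
write_psd_csv <- function(psd, path) {
  stopifnot(inherits(psd, "psd_series"))
  hdr <- c(
    sprintf("# band_hz: %g %g", psd$band_hz[1], psd$band_hz[2]),
    sprintf("# t0_s: %.17g", psd$t0_s),
    sprintf("# normalized: %s", psd$normalized)
  )
  writeLines(c(hdr, "time_s,value"), path)
  utils::write.table(
    data.frame(time_s = psd$t0_s + seq_along(psd$values) - 1,
               value = psd$values),
    path, sep = ",", row.names = FALSE, col.names = FALSE, append = TRUE
  )
  invisible(path)
}

#' @rdname write_psd_csv
#' @export
read_psd_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- meta[startsWith(meta, paste0("# ", key, ":"))]
    trimws(sub(".*:", "", ln[1]))
  }
  band <- as.numeric(strsplit(get_meta("band_hz"), " +")[[1]])
  t0 <- as.numeric(get_meta("t0_s"))
  norm <- identical(get_meta("normalized"), "TRUE")
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  psd_series(df$value, t0_s = t0, band_hz = band, normalized = norm)
}
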
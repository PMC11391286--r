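#' Background-noise spectral profile
#'
#' Mean short-time Fourier magnitude per frequency bin, estimated from a
#' reference segment of the recording known (or assumed) to contain only
#' background noise — typically a quiet stretch in the middle of the night —
#' or, when preparing background-noise measurements, a call-heavy stretch so
#' that calls themselves are gated.
#'
#' @param audio An [audio_night()].
#' @param window Length-2 numeric, `[t_start_s, t_end_s]` of the reference
#'   segment; must lie inside the recording and span at least 10 s.
#' @param fft_size STFT frame length in samples.
#' @param hop STFT hop in samples.
#' @return An object of class `noise_profile`: per-bin mean magnitude
#'   spectrum, with `fft_size` and `sample_rate`.
#' @export
build_noise_profile <- function(audio, window, fft_size = 1024, hop = 512) {
  stopifnot(inherits(audio, "audio_night"))
  if (diff(window) < 10) stop("noise-profile window must span at least 10 s")
  seg <- audio_window(audio, window[1], window[2])$samples
  frames <- stft_frames(seg, fft_size, hop, pad = FALSE)
  w <- hann_window(fft_size)
  mag <- Mod(stats::mvfft(frames * w))
  structure(
    list(magnitude = rowMeans(mag), fft_size = as.integer(fft_size),
         hop = as.integer(hop), sample_rate = audio$sample_rate),
    class = "noise_profile"
  )
}

#' @method print noise_profile
#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> fft %d at %g Hz, mean magnitude %.3g\n",
              x$fft_size, x$sample_rate, mean(x$magnitude)))
  invisible(x)
}

# Slice x into columns of length n with the given hop; optionally pad with
# hop zeros in front (and zeros behind) so overlap-add reconstruction covers
# the edges with unit window sum.
stft_frames <- function(x, n, hop, pad = TRUE) {
  if (pad) x <- c(numeric(hop), x, numeric(n))
  n_frames <- max(1L, floor((length(x) - n) / hop) + 1L)
  need <- (n_frames - 1L) * hop + n
  if (need > length(x)) x <- c(x, numeric(need - length(x)))
  out <- matrix(0, nrow = n, ncol = n_frames)
  for (j in seq_len(n_frames)) {
    out[, j] <- x[((j - 1L) * hop + 1L):((j - 1L) * hop + n)]
  }
  out
}

#' Spectral-gating noise reduction
#'
#' Short-time Fourier transform gating: every STFT bin whose magnitude falls
#' at or below its gate (the noise profile's mean magnitude for that bin
#' times `sensitivity`) is attenuated by `reduction_db`; bins above the gate
#' pass unchanged. The waveform is reconstructed by inverse STFT with
#' overlap-add (periodic Hann analysis window at 50% overlap sums exactly to
#' one), so with `reduction_db = 0` the input is returned unchanged up to
#' numerical round-off.
#'
#' @param audio An [audio_night()]; sample rate must match the profile's.
#' @param profile A [build_noise_profile()] result.
#' @param reduction_db Attenuation depth in dB applied to gated bins.
#' @param sensitivity Gate multiplier on the profile magnitude. The default 3
#'   places the gate above essentially all of the noise magnitude
#'   distribution, so a noise-only segment is attenuated by close to the full
#'   `reduction_db`.
#' @return An [audio_night()] of the same length as the input.
#' @export
spectral_noise_reduce <- function(audio, profile, reduction_db = 6,
                                  sensitivity = 3) {
  stopifnot(inherits(audio, "audio_night"), inherits(profile, "noise_profile"))
  if (!isTRUE(all.equal(audio$sample_rate, profile$sample_rate)))
    stop("sample_rate of audio and noise profile differ")
  n <- profile$fft_size
  hop <- profile$hop
  if (hop * 2L != n) # COLA-exact reconstruction needs 50% Hann overlap
    stop("spectral gating requires hop = fft_size / 2")
  x <- audio$samples
  n_orig <- length(x)
  frames <- stft_frames(x, n, hop, pad = TRUE)
  n_frames <- ncol(frames)
  w <- hann_window(n)
  gate <- profile$magnitude * sensitivity
  att <- 10^(-reduction_db / 20)
  out <- numeric(hop + n_orig + 2L * n)
  chunk <- 1024L
  for (j0 in seq(1L, n_frames, by = chunk)) {
    cols <- j0:min(n_frames, j0 + chunk - 1L)
    X <- stats::mvfft(frames[, cols, drop = FALSE] * w)
    X <- X * (att + (1 - att) * (Mod(X) > gate))
    Y <- Re(stats::mvfft(X, inverse = TRUE)) / n
    # frames of one parity are exactly n apart (hop = n/2), so each parity
    # tiles a contiguous stretch of the output without overlap
    for (parity in 0:1) {
      sel <- which(cols %% 2L == parity)
      if (!length(sel)) next
      start <- (cols[sel[1]] - 1L) * hop
      idx <- (start + 1L):(start + length(sel) * n)
      out[idx] <- out[idx] + as.vector(Y[, sel, drop = FALSE])
    }
  }
  audio_night(out[(hop + 1L):(hop + n_orig)], audio$sample_rate,
              start_clock = audio$start_clock, site = audio$site,
              date = audio$date)
}

#' Trim a PSD series to the roost-occupancy period
#'
#' Calling before the birds arrive and after they depart (flight to and from
#' the site) is removed by keeping the sub-series from the loudest second of
#' the first `head_s` seconds through the loudest second of the last `tail_s`
#' seconds, inclusive. Ties are broken towards the earliest second.
#'
#' @param psd A [psd_series()] longer than `head_s + tail_s`.
#' @param head_s Arrival search window, seconds (default 2 h).
#' @param tail_s Departure search window, seconds (default 2.5 h).
#' @return A [psd_series()] sub-series with `t0_s` updated.
#' @export
trim_to_occupancy <- function(psd, head_s = 7200, tail_s = 9000) {
  stopifnot(inherits(psd, "psd_series"))
  n <- length(psd$values)
  if (n <= head_s + tail_s)
    stop(sprintf("series of %d s too short to trim (head %d + tail %d s)",
                 n, head_s, tail_s))
  i1 <- which.max(psd$values[seq_len(head_s)])
  i2 <- (n - tail_s) + which.max(psd$values[(n - tail_s + 1L):n])
  psd_series(psd$values[i1:i2], t0_s = psd$t0_s + (i1 - 1),
             band_hz = psd$band_hz, normalized = psd$normalized)
}

#' Per-night min-max normalization (nPSD)
#'
#' Rescales a night's PSD series to \[0, 1\] via `(x - min) / (max - min)`,
#' absorbing the constant dB offset induced by recorder position relative to
#' the birds. A constant series maps to all zeros.
#'
#' @param psd A non-empty [psd_series()].
#' @return A [psd_series()] with `normalized = TRUE`.
#' @export
normalize_night <- function(psd) {
  stopifnot(inherits(psd, "psd_series"))
  if (length(psd$values) == 0) stop("empty PSD series")
  rng <- range(psd$values)
  vals <- if (rng[2] > rng[1]) (psd$values - rng[1]) / (rng[2] - rng[1])
          else rep(0, length(psd$values))
  psd_series(vals, t0_s = psd$t0_s, band_hz = psd$band_hz, normalized = TRUE)
}
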
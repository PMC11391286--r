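#' Scenario for one synthetic roost-night
#'
#' Describes the generative ground truth for a single night of roost audio:
#' an evening arrival with dense calling that decays linearly as the birds
#' settle, sparse Poisson calling overnight, a linear pre-departure crescendo
#' ending at the departure anchor, and band-limited background noise.
#' All rates are in calls per hour of scenario time; the decay and crescendo
#' parameters are in calls per hour per hour.
#'
#' @param duration_s Recording length in seconds (default 16 h).
#' @param sample_rate Sampling rate in Hz. Must be at least twice the upper
#'   edge of `call_band_hz` (aliasing).
#' @param arrival_time_s Arrival time, seconds from recording start.
#' @param arrival_peak_rate Calling rate at arrival, calls/h.
#' @param arrival_decay_rate Linear decline of the arrival calling rate,
#'   calls/h per hour; the quiet phase begins when the rate reaches
#'   `night_call_rate`.
#' @param night_call_rate Overnight Poisson calling rate, calls/h.
#' @param departure_anchor_s End of the final mass-calling peak, seconds from
#'   start; calling ceases afterwards.
#' @param predeparture_ramp_s Length of the pre-departure crescendo, seconds.
#' @param predeparture_slope_truth Linear growth of the crescendo calling
#'   rate, calls/h per hour.
#' @param call_band_hz Analysis band containing the calls (Hz).
#' @param chirp_hz Frequency sweep of the synthetic call transient (Hz).
#' @param call_dur_range_s Range of call transient durations (s).
#' @param call_level_db Call transient level (dB re full scale RMS).
#' @param noise_level_db Background-noise floor (dB re full scale RMS).
#' @param noise_band_hz Band of the background noise (Hz).
#' @param anthro_level_db Optional low-frequency (< 1 kHz) anthropogenic
#'   noise component level in dB, or `NULL` for none.
#' @param seed Integer seed; all randomness in [simulate_night()] flows from
#'   it.
#' @return An object of class `night_scenario`.
#' @export
night_scenario <- function(duration_s = 57600, sample_rate = 8000,
                           arrival_time_s = 1800,
                           arrival_peak_rate = 1800,
                           arrival_decay_rate = 1770,
                           night_call_rate = 30,
                           departure_anchor_s = duration_s - 3600,
                           predeparture_ramp_s = 5400,
                           predeparture_slope_truth = 2400,
                           call_band_hz = c(1000, 3000),
                           chirp_hz = c(1200, 2800),
                           call_dur_range_s = c(0.2, 0.5),
                           call_level_db = -15,
                           noise_level_db = -45,
                           noise_band_hz = c(0, 4000),
                           anthro_level_db = NULL,
                           seed = 1L) {
  sc <- structure(as.list(environment()), class = "night_scenario")
  if (!(sc$arrival_time_s < sc$departure_anchor_s &&
        sc$departure_anchor_s <= sc$duration_s))
    stop("need arrival_time_s < departure_anchor_s <= duration_s")
  if (sc$sample_rate < 2 * sc$call_band_hz[2])
    stop("sample_rate below twice the call band's upper edge (aliasing)")
  if (sc$call_band_hz[1] < 0 || sc$call_band_hz[2] > sc$sample_rate / 2)
    stop("call_band_hz must lie within [0, sample_rate/2]")
  if (sc$arrival_peak_rate < 0 || sc$night_call_rate < 0 ||
      sc$arrival_decay_rate < 0 || sc$predeparture_slope_truth < 0)
    stop("rates must be non-negative")
  sc
}

#' @method print night_scenario
#' @export
print.night_scenario <- function(x, ...) {
  cat(sprintf(paste0("<night_scenario> %.0f s at %g Hz; arrival %.0f s, ",
                     "departure anchor %.0f s, night rate %g calls/h\n"),
              x$duration_s, x$sample_rate, x$arrival_time_s,
              x$departure_anchor_s, x$night_call_rate))
  invisible(x)
}

#' Compressed-time night scenario
#'
#' Scales a nominal 16 h scenario onto a shorter timeline: all times are
#' multiplied by `scale`, per-hour rates divided by `scale` and the two
#' per-hour-squared rate derivatives divided by `scale^2`, so expected call
#' counts per phase are preserved while audio synthesis stays desk-sized.
#' Call transient durations are physical and are not scaled.
#'
#' @param scale Time-compression factor in (0, 1\]; `1/60` maps 16 h onto
#'   16 min.
#' @param ... Overrides passed to [night_scenario()], interpreted on the
#'   nominal (uncompressed) timescale.
#' @return A `night_scenario` on the compressed timeline.
#' @export
compressed_night_scenario <- function(scale = 1 / 60, ...) {
  stopifnot(scale > 0, scale <= 1)
  sc <- night_scenario(...)
  sc$duration_s <- sc$duration_s * scale
  sc$arrival_time_s <- sc$arrival_time_s * scale
  sc$departure_anchor_s <- sc$departure_anchor_s * scale
  sc$predeparture_ramp_s <- sc$predeparture_ramp_s * scale
  sc$arrival_peak_rate <- sc$arrival_peak_rate / scale
  sc$night_call_rate <- sc$night_call_rate / scale
  sc$arrival_decay_rate <- sc$arrival_decay_rate / scale^2
  sc$predeparture_slope_truth <- sc$predeparture_slope_truth / scale^2
  sc
}

# Phase boundaries on the scenario's own timeline.
night_phase_bounds <- function(sc) {
  ramp_start <- max(sc$arrival_time_s,
                    sc$departure_anchor_s - sc$predeparture_ramp_s)
  quiet_start <- if (sc$arrival_peak_rate <= sc$night_call_rate) {
    sc$arrival_time_s
  } else if (sc$arrival_decay_rate > 0) {
    sc$arrival_time_s +
      3600 * (sc$arrival_peak_rate - sc$night_call_rate) / sc$arrival_decay_rate
  } else {
    ramp_start
  }
  quiet_start <- min(quiet_start, ramp_start)
  list(quiet_start_s = quiet_start, ramp_start_s = ramp_start)
}

# Inhomogeneous-Poisson call times for one phase by thinning.
# rate_fun takes time (s) and returns calls/h.
sample_phase_calls <- function(t0, t1, rate_fun, rate_max) {
  len <- t1 - t0
  if (len <= 0 || rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max / 3600 * len)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rate_fun(cand) / rate_max
  cand[keep]
}

#' Simulate one roost-night
#'
#' Draws call times from the scenario's three-phase rate function (arrival
#' decay, overnight Poisson, pre-departure crescendo; silence outside them)
#' and, unless `synthesize = FALSE`, renders a waveform as band-limited
#' coloured background noise plus a Hann-enveloped linear chirp per call.
#'
#' @param scenario A [night_scenario()].
#' @param synthesize Render the waveform? Set `FALSE` to obtain only call
#'   times and ground truth, which is cheap even at the nominal 16 h scale.
#' @return A list with `audio` (an [audio_night()], or `NULL`) and `truth`:
#'   call times and durations, per-call phase labels, per-phase realized
#'   counts, the phase boundaries and the scenario.
#' @examples
#' sc <- compressed_night_scenario(scale = 1 / 240, seed = 7)
#' night <- simulate_night(sc)
#' night$truth$counts
#' @export
simulate_night <- function(scenario, synthesize = TRUE) {
  stopifnot(inherits(scenario, "night_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    b <- night_phase_bounds(sc)
    arr <- sample_phase_calls(
      sc$arrival_time_s, b$quiet_start_s,
      function(t) pmax(sc$night_call_rate,
                       sc$arrival_peak_rate -
                         sc$arrival_decay_rate * (t - sc$arrival_time_s) / 3600),
      sc$arrival_peak_rate
    )
    ngt <- sample_phase_calls(
      b$quiet_start_s, b$ramp_start_s,
      function(t) rep(sc$night_call_rate, length(t)),
      sc$night_call_rate
    )
    ramp_end_rate <- sc$night_call_rate + sc$predeparture_slope_truth *
      (sc$departure_anchor_s - b$ramp_start_s) / 3600
    dep <- sample_phase_calls(
      b$ramp_start_s, sc$departure_anchor_s,
      function(t) sc$night_call_rate +
        sc$predeparture_slope_truth * (t - b$ramp_start_s) / 3600,
      ramp_end_rate
    )
    times <- c(arr, ngt, dep)
    phase <- rep(c("arrival", "night", "predeparture"),
                 c(length(arr), length(ngt), length(dep)))
    ord <- order(times)
    times <- times[ord]
    phase <- phase[ord]
    durs <- stats::runif(length(times), sc$call_dur_range_s[1],
                         sc$call_dur_range_s[2])
    audio <- if (synthesize) synth_waveform(sc, times, durs) else NULL
    list(
      audio = audio,
      truth = list(
        call_times_s = times,
        call_durations_s = durs,
        phase = phase,
        counts = c(arrival = length(arr), night = length(ngt),
                   predeparture = length(dep)),
        quiet_start_s = b$quiet_start_s,
        ramp_start_s = b$ramp_start_s,
        scenario = sc
      )
    )
  })
}

# White noise restricted to a frequency band via FFT masking, rescaled to the
# requested RMS level.
band_limited_noise <- function(n, fs, band, level_db) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * (10^(level_db / 20) / r)
  x
}

synth_waveform <- function(sc, times, durs) {
  fs <- sc$sample_rate
  n <- as.integer(round(sc$duration_s * fs))
  x <- band_limited_noise(n, fs, sc$noise_band_hz, sc$noise_level_db)
  if (!is.null(sc$anthro_level_db) && is.finite(sc$anthro_level_db)) {
    x <- x + band_limited_noise(n, fs, c(0, 1000), sc$anthro_level_db)
  }
  amp <- 10^(sc$call_level_db / 20) * 4 / sqrt(3) # Hann-envelope RMS correction
  f0 <- sc$chirp_hz[1]
  f1 <- sc$chirp_hz[2]
  for (i in seq_along(times)) {
    d <- durs[i]
    m <- as.integer(round(d * fs))
    i0 <- as.integer(round(times[i] * fs)) + 1L
    if (i0 + m - 1L > n) m <- n - i0 + 1L
    if (m < 2L) next
    tt <- (0:(m - 1L)) / fs
    chirp <- sin(2 * pi * (f0 * tt + (f1 - f0) / (2 * d) * tt^2))
    env <- hann_window(m)
    x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + amp * env * chirp
  }
  audio_night(x, fs, start_clock = "16:00", site = "synthetic",
              date = as.Date("2022-01-15"))
}
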
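# OLS slope of values against time in seconds, reported per hour.
ols_slope_per_hour <- function(values) {
  t_s <- seq_along(values) - 1
  3600 * stats::cov(t_s, values) / stats::var(t_s)
}

#' Post-arrival settling slope
#'
#' Ordinary-least-squares slope of the first `window_s` values of a
#' normalized per-second series against time, reported per hour (normalized
#' dB Hz^-1 h^-1). Negative slopes mean the birds are settling; slightly
#' positive slopes occur on nights when calling does not die down within the
#' window and are retained as-is.
#'
#' @param npsd A normalized, trimmed [psd_series()].
#' @param window_s Regression window from the start of the series (default
#'   1 h).
#' @return The slope (numeric scalar).
#' @export
settling_slope <- function(npsd, window_s = 3600) {
  stopifnot(inherits(npsd, "psd_series"))
  if (length(npsd$values) < window_s)
    stop(sprintf("series of %d s shorter than settling window of %d s",
                 length(npsd$values), window_s))
  ols_slope_per_hour(npsd$values[seq_len(window_s)])
}

#' Pre-departure calling slope
#'
#' OLS slope of the final `window_s` values against time, per hour. Steeper
#' positive slopes indicate a building vocal consensus before the mass
#' departure.
#'
#' @inheritParams settling_slope
#' @param window_s Regression window ending at the series end (default
#'   1.5 h).
#' @return The slope (numeric scalar).
#' @export
predeparture_slope <- function(npsd, window_s = 5400) {
  stopifnot(inherits(npsd, "psd_series"))
  n <- length(npsd$values)
  if (n < window_s)
    stop(sprintf("series of %d s shorter than pre-departure window of %d s",
                 n, window_s))
  ols_slope_per_hour(npsd$values[(n - window_s + 1L):n])
}

#' Proportion of the night spent calling
#'
#' Fraction of seconds whose nPSD meets or exceeds `threshold`, within the
#' overnight window running from `settle_offset_s` after the start of the
#' trimmed series to `predeparture_exclusion_s` before its end — i.e. after
#' the birds have settled post-arrival until the pre-departure crescendo
#' window begins.
#'
#' @param npsd A normalized, trimmed [psd_series()].
#' @param threshold nPSD threshold separating calling from background
#'   (default 0.2; 0.4 for the conservative robustness variant).
#' @param settle_offset_s Seconds skipped at the start (default 1 h).
#' @param predeparture_exclusion_s Seconds excluded at the end (default
#'   1.5 h).
#' @return Proportion in \[0, 1\].
#' @export
night_calling_proportion <- function(npsd, threshold = 0.2,
                                     settle_offset_s = 3600,
                                     predeparture_exclusion_s = 5400) {
  stopifnot(inherits(npsd, "psd_series"))
  n <- length(npsd$values)
  i0 <- settle_offset_s + 1L
  i1 <- n - predeparture_exclusion_s
  if (i1 < i0) stop("overnight window is empty for this series")
  mean(npsd$values[i0:i1] >= threshold)
}

#' Onset of continuous departure calling
#'
#' Deterministic surrogate for the spectrogram-inspection judgement of when
#' continuous departure calling begins: the first second within the final
#' `window_s` of the series whose nPSD stays at or above `threshold` for at
#' least `run_s` consecutive seconds. Falls back to the start of the final
#' window if no such run exists.
#'
#' @inheritParams night_calling_proportion
#' @param window_s Search window at the end of the series (default 1.5 h).
#' @param run_s Required run length in seconds.
#' @return Onset time in seconds on the series' time axis (`t0_s`-based).
#' @export
departure_calling_onset <- function(npsd, threshold = 0.2, window_s = 5400,
                                    run_s = 60) {
  stopifnot(inherits(npsd, "psd_series"))
  n <- length(npsd$values)
  w0 <- max(1L, n - as.integer(window_s) + 1L)
  v <- npsd$values[w0:n] >= threshold
  r <- rle(v)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_s)
  idx <- if (length(hit)) ends[hit[1]] - r$lengths[hit[1]] + 1L else 1L
  npsd$t0_s + (w0 - 1L) + (idx - 1L)
}

#' Background-noise levels around the night's three focal periods
#'
#' Measures local background noise in the hour before arrival, a two-hour
#' window during the night, and the hour before continuous departure calling
#' begins. To keep the birds' own calls out of the measurement, a noise
#' profile is taken from a period of frequent calling (around the arrival
#' anchor) and used to noise-reduce each window; band power over
#' `band` (0-4000 Hz by default) is then computed per second, the three
#' windows are min-max normalized jointly, and per-window means returned.
#'
#' @param raw_audio The unreduced [audio_night()].
#' @param arrival_anchor_s Arrival peak time, seconds from recording start.
#' @param departure_calling_onset_s Onset of continuous departure calling,
#'   seconds from recording start (see [departure_calling_onset()]).
#' @param night_window_s Length-2 numeric: the overnight window in seconds
#'   from recording start. Defaults to clock 23:00-01:00 derived from the
#'   recording's `start_clock`.
#' @param window_len_s Length of the pre-arrival and pre-departure windows.
#' @param profile_window_s Length-2 window for the call-period noise
#'   profile; defaults to the 5 minutes after the arrival anchor.
#' @param band Analysis band in Hz.
#' @param reduction_db Noise-reduction depth in dB.
#' @param fft_size,hop STFT parameters for the reduction.
#' @return Named numeric vector: `noise_prearrival`, `noise_overnight`,
#'   `noise_predeparture` (mean joint-normalized band PSD per window).
#' @export
background_noise_levels <- function(raw_audio, arrival_anchor_s,
                                    departure_calling_onset_s,
                                    night_window_s = NULL,
                                    window_len_s = 3600,
                                    profile_window_s = NULL,
                                    band = c(0, 4000),
                                    reduction_db = 6,
                                    fft_size = 1024, hop = 512) {
  stopifnot(inherits(raw_audio, "audio_night"))
  dur <- audio_duration_s(raw_audio)
  band[2] <- min(band[2], raw_audio$sample_rate / 2)
  night_window_s <- night_window_s %||% {
    t0 <- clock_offset_s(raw_audio, "23:00")
    c(t0, t0 + 7200)
  }
  profile_window_s <- profile_window_s %||%
    c(arrival_anchor_s, min(arrival_anchor_s + 300, dur))
  windows <- list(
    noise_prearrival = c(arrival_anchor_s - window_len_s, arrival_anchor_s),
    noise_overnight = night_window_s,
    noise_predeparture = c(departure_calling_onset_s - window_len_s,
                           departure_calling_onset_s)
  )
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (w[1] < 0 || w[2] > dur)
      stop(sprintf("%s window [%g, %g] s outside recording of %g s",
                   nm, w[1], w[2], dur))
  }
  profile <- build_noise_profile(raw_audio, profile_window_s,
                                 fft_size = fft_size, hop = hop)
  series <- lapply(windows, function(w) {
    seg <- audio_window(raw_audio, w[1], w[2])
    red <- spectral_noise_reduce(seg, profile, reduction_db = reduction_db)
    band_psd_series(red, band)$values
  })
  all_vals <- unlist(series, use.names = FALSE)
  rng <- range(all_vals)
  norm <- if (rng[2] > rng[1]) {
    lapply(series, function(v) (v - rng[1]) / (rng[2] - rng[1]))
  } else {
    lapply(series, function(v) rep(0, length(v)))
  }
  vapply(norm, mean, numeric(1))
}

#' Assemble the full per-night metric row
#'
#' Runs the complete acoustic pipeline for one night — noise profile from a
#' quiet mid-night window, 6 dB spectral gating, band PSD over the call
#' band, occupancy trimming, per-night normalization — then derives the
#' three calling statistics and the three background-noise covariates, and
#' joins the supplied covariates.
#'
#' @param audio An [audio_night()].
#' @param covariates Named list or one-row data frame of per-night
#'   covariates (e.g. `roost_size`, `temp_mean`, `wind_mean`, `rain`,
#'   `light_mean`). A missing `light_mean` is recorded as `NA` (some sites
#'   have no light logger).
#' @param config A [pipeline_config()]; its window lengths must suit the
#'   recording's timescale (use [scale_pipeline_config()] for
#'   compressed-time synthetic nights).
#' @return A one-row data frame (the night's metrics and covariates).
#' @export
assemble_night_metrics <- function(audio, covariates = list(),
                                   config = pipeline_config()) {
  stopifnot(inherits(audio, "audio_night"))
  cfg <- config
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  profile_win <- cfg$noise_profile_window_s %||% {
    t0 <- clock_offset_s(audio, "02:00")
    c(t0, t0 + 300)
  }
  profile <- stage("noise_profile",
                   build_noise_profile(audio, profile_win,
                                       fft_size = cfg$fft_size,
                                       hop = cfg$hop))
  reduced <- stage("noise_reduce",
                   spectral_noise_reduce(audio, profile,
                                         reduction_db = cfg$noise_reduction_db,
                                         sensitivity = cfg$gate_sensitivity))
  psd <- stage("band_psd", band_psd_series(reduced, cfg$band_call_hz))
  trimmed <- stage("trim", trim_to_occupancy(psd, cfg$head_trim_s,
                                             cfg$tail_trim_s))
  npsd <- stage("normalize", normalize_night(trimmed))
  settle <- stage("settling_slope", settling_slope(npsd, cfg$settle_window_s))
  predep <- stage("predeparture_slope",
                  predeparture_slope(npsd, cfg$predeparture_window_s))
  ncp <- stage("night_calling_proportion",
               night_calling_proportion(npsd, cfg$call_threshold,
                                        cfg$settle_window_s,
                                        cfg$predeparture_window_s))
  ncp_alt <- stage("night_calling_proportion",
                   night_calling_proportion(npsd, cfg$alt_threshold,
                                            cfg$settle_window_s,
                                            cfg$predeparture_window_s))
  onset <- stage("departure_onset",
                 departure_calling_onset(npsd, cfg$call_threshold,
                                         cfg$predeparture_window_s))
  noise <- stage("background_noise", {
    dur <- audio_duration_s(audio)
    arrival_anchor <- npsd$t0_s
    night_win <- cfg$night_noise_window_s %||% NULL
    window_len <- cfg$noise_window_len_s
    background_noise_levels(
      audio,
      arrival_anchor_s = max(arrival_anchor, window_len),
      departure_calling_onset_s = min(max(onset, window_len), dur),
      night_window_s = night_win,
      window_len_s = window_len,
      band = cfg$band_noise_hz,
      reduction_db = cfg$noise_reduction_db,
      fft_size = cfg$fft_size, hop = cfg$hop
    )
  })
  cov <- as.list(covariates)
  out <- data.frame(
    site = audio$site, date = audio$date,
    month = format(audio$date, "%b"),
    settle_slope = settle,
    night_call_prop = ncp,
    night_call_prop_alt = ncp_alt,
    predeparture_slope = predep,
    noise_prearrival = noise[["noise_prearrival"]],
    noise_overnight = noise[["noise_overnight"]],
    noise_predeparture = noise[["noise_predeparture"]],
    roost_size = cov$roost_size %||% NA_real_,
    temp_mean = cov$temp_mean %||% NA_real_,
    wind_mean = cov$wind_mean %||% NA_real_,
    rain = cov$rain %||% NA_real_,
    light_mean = cov$light_mean %||% NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write / read per-night metrics tables
#'
#' Tidy CSV, one row per night, fixed column names as produced by
#' [assemble_night_metrics()].
#'
#' @param metrics Data frame of per-night metrics.
#' @param path File path.
#' @return `write_metrics_csv()` returns `path` invisibly;
#'   `read_metrics_csv()` returns the data frame (dates restored).
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}
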
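#' Pipeline configuration
#'
#' All fixed constants of the acoustic and behavioural analysis in one
#' place, overridable individually or from YAML. Defaults are the analysis
#' constants of the roost study design: 1000-3000 Hz call band, 0-4000 Hz
#' noise band, 6 dB noise reduction, 2 h / 2.5 h occupancy trimming, 1 h
#' settling window, 1.5 h pre-departure window, calling thresholds 0.2 and
#' 0.4, 10 s group window and 2 s group gap.
#'
#' @param band_call_hz Call analysis band (Hz).
#' @param band_noise_hz Background-noise analysis band (Hz).
#' @param noise_reduction_db Spectral-gating attenuation depth (dB).
#' @param gate_sensitivity Gate multiplier on profile magnitude.
#' @param fft_size,hop STFT parameters for gating.
#' @param head_trim_s,tail_trim_s Occupancy trimming windows (s).
#' @param settle_window_s Settling regression window (s).
#' @param predeparture_window_s Pre-departure regression window (s).
#' @param call_threshold,alt_threshold nPSD calling thresholds.
#' @param group_window_s,group_gap_s Departure-group segmentation window and
#'   gap (s).
#' @param noise_profile_window_s Optional `[start, end]` (s) for the quiet
#'   noise-profile window; `NULL` uses clock 02:00-04:00 (first 5 min).
#' @param night_noise_window_s Optional `[start, end]` (s) for the overnight
#'   background-noise window; `NULL` uses clock 23:00-01:00.
#' @param noise_window_len_s Length of the pre-arrival and pre-departure
#'   noise windows (s).
#' @param seed Integer seed used by simulation-backed runs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_call_hz = c(1000, 3000),
                            band_noise_hz = c(0, 4000),
                            noise_reduction_db = 6,
                            gate_sensitivity = 3,
                            fft_size = 1024, hop = 512,
                            head_trim_s = 7200, tail_trim_s = 9000,
                            settle_window_s = 3600,
                            predeparture_window_s = 5400,
                            call_threshold = 0.2, alt_threshold = 0.4,
                            group_window_s = 10, group_gap_s = 2,
                            noise_profile_window_s = NULL,
                            night_noise_window_s = NULL,
                            noise_window_len_s = 3600,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (any(c(cfg$head_trim_s, cfg$tail_trim_s, cfg$settle_window_s,
            cfg$predeparture_window_s, cfg$noise_window_len_s,
            cfg$group_window_s) <= 0))
    stop("all windows must be positive")
  if (any(c(cfg$call_threshold, cfg$alt_threshold) <= 0) ||
      any(c(cfg$call_threshold, cfg$alt_threshold) >= 1))
    stop("thresholds must lie in (0, 1)")
  if (cfg$band_call_hz[1] >= cfg$band_call_hz[2] ||
      cfg$band_noise_hz[1] >= cfg$band_noise_hz[2])
    stop("bands must be increasing [low, high] pairs")
  cfg
}

#' @method print pipeline_config
#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> call band %g-%g Hz, noise band ",
                     "%g-%g Hz, %g dB reduction, thresholds %g/%g\n"),
              x$band_call_hz[1], x$band_call_hz[2], x$band_noise_hz[1],
              x$band_noise_hz[2], x$noise_reduction_db, x$call_threshold,
              x$alt_threshold))
  invisible(x)
}

#' Rescale a configuration for compressed-time audio
#'
#' Multiplies every window length by `scale` so the configuration matches
#' audio generated with [compressed_night_scenario()]. Integer-second
#' windows are rounded and kept at least 1 s. The clock-derived defaults
#' are replaced by explicit scaled windows (02:00-04:00 noise profile and
#' 23:00-01:00 overnight noise on the nominal 16:00-start timeline).
#'
#' @param config A [pipeline_config()] on the nominal timescale.
#' @param scale Time-compression factor in (0, 1\].
#' @return A scaled `pipeline_config`.
#' @export
scale_pipeline_config <- function(config, scale) {
  stopifnot(inherits(config, "pipeline_config"), scale > 0, scale <= 1)
  sc <- function(x) max(1L, as.integer(round(x * scale)))
  config$head_trim_s <- sc(config$head_trim_s)
  config$tail_trim_s <- sc(config$tail_trim_s)
  config$settle_window_s <- sc(config$settle_window_s)
  config$predeparture_window_s <- sc(config$predeparture_window_s)
  config$noise_window_len_s <- sc(config$noise_window_len_s)
  pw <- (config$noise_profile_window_s %||% c(36000, 36300)) * scale
  if (diff(pw) < 10) pw[2] <- pw[1] + 10 # profile needs >= 10 s of audio
  config$noise_profile_window_s <- pw
  config$night_noise_window_s <-
    (config$night_noise_window_s %||% c(25200, 32400)) * scale
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  ok <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[ok])
}

#' Run the full study pipeline end to end
#'
#' Either analyses a directory of per-night WAV recordings with a covariate
#' table (and optional departure-event tables), or simulates a full season
#' from a [season_truth()]. Produces the per-night metrics table, departure
#' summaries, the five-model report suite, and a run manifest (configuration,
#' seed, package version, per-stage log and output content hashes). Failing
#' nights are logged and excluded, not fatal, mirroring field practice of
#' excluding corrupted recordings.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Directory holding `<site>_<date>.wav` files, a
#'   `covariates.csv` (columns `site`, `date`, `roost_size`, `temp_mean`,
#'   `wind_mean`, `rain`, optionally `light_mean`, `start_clock`) and
#'   optionally `<site>_<date>_events.csv` departure tables. Ignored when
#'   `simulate` is given.
#' @param simulate A [season_truth()] to simulate instead of reading audio.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param seed Integer seed for simulation-backed runs (defaults to the
#'   config's seed).
#' @param fit_models Fit the model suite? Requires enough analysable nights.
#' @return A list with `metrics`, `departures`, `suite` (or `NULL`),
#'   `exclusions` (per-night failure log) and `manifest`.
#' @export
run_end_to_end <- function(config = pipeline_config(), input_dir = NULL,
                           simulate = NULL, out_dir = NULL,
                           seed = config$seed, fit_models = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  exclusions <- data.frame(night = character(0), stage_error = character(0),
                           stringsAsFactors = FALSE)
  departures <- NULL
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "season_truth"))
    metrics <- simulate_season(simulate, seed = seed)
  } else {
    if (is.null(input_dir)) stop("provide input_dir or a simulation truth")
    wavs <- sort(list.files(input_dir, pattern = "\\.wav$",
                            full.names = TRUE))
    wavs <- wavs[!grepl("_events", basename(wavs))]
    if (length(wavs) == 0) stop("no WAV files found in ", input_dir)
    cov_path <- file.path(input_dir, "covariates.csv")
    covs <- if (file.exists(cov_path))
      utils::read.csv(cov_path, stringsAsFactors = FALSE) else NULL
    rows <- list()
    dep_rows <- list()
    for (w in wavs) {
      night_id <- sub("\\.wav$", "", basename(w))
      parts <- strsplit(night_id, "_")[[1]]
      site <- parts[1]
      date <- as.Date(paste(parts[-1], collapse = "-"))
      cov_row <- if (!is.null(covs))
        covs[covs$site == site & as.Date(covs$date) == date, , drop = FALSE]
      else NULL
      res <- tryCatch({
        audio <- read_wav(w, site = site, date = date,
                          start_clock = if (!is.null(cov_row) &&
                                            nrow(cov_row) &&
                                            "start_clock" %in% names(cov_row))
                            cov_row$start_clock[1] else "16:00")
        assemble_night_metrics(audio,
                               covariates = if (!is.null(cov_row) &&
                                                nrow(cov_row))
                                 as.list(cov_row[1, ]) else list(),
                               config = config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(night = night_id,
                                       stage_error = conditionMessage(res),
                                       stringsAsFactors = FALSE))
        next
      }
      rows[[night_id]] <- res
      ev_path <- file.path(input_dir, paste0(night_id, "_events.csv"))
      if (file.exists(ev_path) && !is.na(res$roost_size)) {
        seg <- segment_group_departures(read_events_csv(ev_path),
                                        config$group_window_s,
                                        config$group_gap_s)
        ds <- departure_summary(seg, res$roost_size)
        ds$site <- site
        ds$date <- date
        dep_rows[[night_id]] <- ds
      }
    }
    if (length(rows) == 0) stop("no nights could be analysed")
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    if (length(dep_rows)) {
      departures <- do.call(rbind, dep_rows)
      rownames(departures) <- NULL
    }
  }
  suite <- NULL
  if (fit_models) {
    suite <- tryCatch(
      run_prediction_suite(metrics, departures = departures),
      error = function(e) {
        warning("model suite not fitted: ", conditionMessage(e))
        NULL
      }
    )
  }
  manifest <- list(
    package = "roostcall",
    version = as.character(utils::packageVersion("roostcall")),
    seed = seed,
    mode = if (is.null(simulate)) "input_dir" else "simulate",
    config = config[setdiff(names(config), character(0))],
    n_nights = nrow(metrics),
    n_excluded = nrow(exclusions),
    exclusions = exclusions
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(out_dir, "night_metrics.csv"))
    if (!is.null(departures))
      utils::write.csv(departures,
                       file.path(out_dir, "departure_summaries.csv"),
                       row.names = FALSE)
    if (!is.null(suite))
      write_suite_json(suite, file.path(out_dir, "model_reports.json"))
    hash_files <- list.files(out_dir, full.names = TRUE,
                             pattern = "\\.(csv|json)$")
    hash_files <- hash_files[basename(hash_files) != "manifest.json"]
    manifest$output_hashes <- as.list(tools::md5sum(hash_files))
    names(manifest$output_hashes) <- basename(hash_files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  list(metrics = metrics, departures = departures, suite = suite,
       exclusions = exclusions, manifest = manifest)
}
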
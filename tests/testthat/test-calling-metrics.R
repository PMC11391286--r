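make_npsd <- function(values) {
  psd_series(values, band_hz = c(1000, 3000), normalized = TRUE)
}

test_that("slopes reproduce exact lines and constants", {
  # nPSD falling linearly 1 -> 0 across the first hour: -1.0 per hour
  t <- 0:3599
  falling <- make_npsd(c(1 - t / 3600, runif(1000)))
  expect_equal(settling_slope(falling), -1, tolerance = 1e-12)
  constant <- make_npsd(rep(0.4, 6000))
  expect_equal(settling_slope(constant), 0, tolerance = 1e-12)
  # final 1.5 h rising 0 -> 1: +1/1.5 per hour
  rising <- make_npsd(c(runif(1000), (0:5399) / 5400))
  expect_equal(predeparture_slope(rising), 3600 / 5400, tolerance = 1e-12)
  expect_equal(predeparture_slope(constant), 0, tolerance = 1e-12)
  expect_error(settling_slope(make_npsd(runif(100))), "shorter")
  expect_error(predeparture_slope(make_npsd(runif(100))), "shorter")
})

test_that("slopes are shift invariant and scale equivariant", {
  set.seed(31)
  for (i in 1:10) {
    v <- runif(4000)
    s <- settling_slope(make_npsd(v))
    expect_equal(settling_slope(make_npsd(v + 0.3)), s, tolerance = 1e-9)
    expect_equal(settling_slope(make_npsd(v * 2.5)), s * 2.5,
                 tolerance = 1e-9)
  }
})

test_that("settling slope recovers the generator's planted decay", {
  # arrival calling decays linearly to silence across the settle window;
  # with nPSD spanning [0, 1], the planted normalized decay is -1 per
  # settle-window length
  fix <- synthetic_night_fixture()
  cfg <- fix$config
  psd <- band_psd_series(fix$night$audio, fix$scenario$call_band_hz)
  npsd <- normalize_night(trim_to_occupancy(psd, cfg$head_trim_s,
                                            cfg$tail_trim_s))
  s <- settling_slope(npsd, cfg$settle_window_s)
  expect_lt(s, 0)
  # steeper planted crescendo gives a strictly larger pre-departure slope
  # on paired nights. Steepness here means the same peak calling intensity
  # reached over a shorter ramp (a sharper consensus), so both nights of a
  # pair share the same normalization maximum; a gradual ramp is already
  # elevated when the regression window opens and measures flatter
  cfg2 <- scale_pipeline_config(pipeline_config(), 1 / 240)
  slope_for <- function(ramp_s, seed) {
    sc <- compressed_night_scenario(
      scale = 1 / 240, seed = seed,
      predeparture_ramp_s = ramp_s,
      predeparture_slope_truth = 3600 / (ramp_s / 3600))
    night <- simulate_night(sc)
    p <- band_psd_series(night$audio, sc$call_band_hz)
    np <- normalize_night(trim_to_occupancy(p, cfg2$head_trim_s,
                                            cfg2$tail_trim_s))
    predeparture_slope(np, cfg2$predeparture_window_s)
  }
  for (seed in 101:110) {
    expect_gt(slope_for(1350, seed), slope_for(5400, seed),
              label = paste("steeper crescendo, seed", seed))
  }
})

test_that("night calling proportion handles extremes and thresholds", {
  zeros <- make_npsd(c(rep(1, 10), numeric(200), rep(1, 20)))
  expect_identical(
    night_calling_proportion(zeros, settle_offset_s = 10,
                             predeparture_exclusion_s = 20), 0)
  ones <- make_npsd(rep(1, 230))
  expect_identical(
    night_calling_proportion(ones, settle_offset_s = 10,
                             predeparture_exclusion_s = 20), 1)
  expect_error(
    night_calling_proportion(make_npsd(runif(25)), settle_offset_s = 20,
                             predeparture_exclusion_s = 20), "empty")
})

test_that("proportion is non-increasing in the threshold", {
  set.seed(17)
  for (i in 1:20) {
    v <- make_npsd(runif(300))
    p02 <- night_calling_proportion(v, 0.2, settle_offset_s = 30,
                                    predeparture_exclusion_s = 45)
    p04 <- night_calling_proportion(v, 0.4, settle_offset_s = 30,
                                    predeparture_exclusion_s = 45)
    expect_lte(p04, p02)
  }
})

test_that("statistics agree with naive loop recomputation", {
  set.seed(23)
  for (i in 1:50) {
    v <- runif(500)
    np <- make_npsd(v)
    # naive slope over the first 100 s
    w <- v[1:100]
    tt <- 0:99
    num <- 0
    den <- 0
    for (j in seq_along(w)) {
      num <- num + (tt[j] - mean(tt)) * (w[j] - mean(w))
      den <- den + (tt[j] - mean(tt))^2
    }
    expect_equal(settling_slope(np, 100), 3600 * num / den,
                 tolerance = 1e-9)
    # naive tail slope over the last 150 s
    w2 <- v[(length(v) - 149):length(v)]
    num2 <- 0
    for (j in seq_along(w2)) num2 <- num2 + (tt2 <- j - 1 - 74.5) * (w2[j] - mean(w2))
    den2 <- sum(((seq_along(w2) - 1) - 74.5)^2)
    expect_equal(predeparture_slope(np, 150), 3600 * num2 / den2,
                 tolerance = 1e-9)
    # naive threshold count
    cnt <- 0
    for (j in 31:(length(v) - 45)) if (v[j] >= 0.2) cnt <- cnt + 1
    expect_equal(
      night_calling_proportion(np, 0.2, settle_offset_s = 30,
                               predeparture_exclusion_s = 45),
      cnt / length(31:(length(v) - 45)), tolerance = 1e-9)
  }
})

test_that("planted overnight call seconds set the measured proportion", {
  fix <- synthetic_night_fixture()
  sc <- fix$scenario
  cfg <- fix$config
  night <- fix$night
  psd <- band_psd_series(night$audio, sc$call_band_hz)
  npsd <- normalize_night(trim_to_occupancy(psd, cfg$head_trim_s,
                                            cfg$tail_trim_s))
  prop <- night_calling_proportion(npsd, cfg$call_threshold,
                                   cfg$settle_window_s,
                                   cfg$predeparture_window_s)
  # planted fraction over the same overnight window, on the trimmed axis
  w0 <- npsd$t0_s + cfg$settle_window_s
  w1 <- npsd$t0_s + length(npsd$values) - cfg$predeparture_window_s
  secs <- planted_call_seconds(night$truth) - 1 # to 0-based seconds
  planted <- sum(secs >= w0 & secs < w1) / (w1 - w0)
  expect_lt(abs(prop - planted), 0.02)
})

test_that("departure-calling onset finds the first sustained run", {
  v <- numeric(600)
  v[501:600] <- 1 # sustained calling over the last 100 s
  np <- make_npsd(v)
  expect_identical(departure_calling_onset(np, 0.2, window_s = 300,
                                           run_s = 60), 500)
  # no sustained run: falls back to the start of the final window
  expect_identical(departure_calling_onset(make_npsd(numeric(600)), 0.2,
                                           window_s = 300, run_s = 60), 300)
})

test_that("background noise windows reproduce the planted ordering", {
  fs <- 8000
  level <- function(db, n, seed) {
    set.seed(seed)
    z <- rnorm(n * fs)
    z * 10^(db / 20) / sqrt(mean(z^2))
  }
  # 300 s with planted noise at -30 / -40 / -50 dB in the three windows
  x <- c(level(-30, 60, 1), level(-45, 60, 2), level(-40, 60, 3),
         level(-45, 60, 4), level(-50, 60, 5))
  an <- audio_night(x, fs)
  res <- background_noise_levels(an, arrival_anchor_s = 60,
                                 departure_calling_onset_s = 300,
                                 night_window_s = c(120, 180),
                                 window_len_s = 60,
                                 profile_window_s = c(240, 255))
  expect_gt(res[["noise_prearrival"]], res[["noise_overnight"]])
  expect_gt(res[["noise_overnight"]], res[["noise_predeparture"]])
  expect_error(
    background_noise_levels(an, arrival_anchor_s = 30,
                            departure_calling_onset_s = 300,
                            night_window_s = c(120, 180), window_len_s = 60,
                            profile_window_s = c(240, 255)),
    "outside")
  # silence: all three means equal (degenerate all-zero normalization)
  silent <- audio_night(numeric(300 * fs), fs)
  res0 <- background_noise_levels(silent, 60, 300,
                                  night_window_s = c(120, 180),
                                  window_len_s = 60,
                                  profile_window_s = c(240, 255))
  expect_true(all(res0 == res0[1]))
})

test_that("metric assembly is deterministic and flags missing light", {
  fix <- synthetic_night_fixture()
  m1 <- assemble_night_metrics(fix$night$audio,
                               covariates = list(roost_size = 300,
                                                 temp_mean = 4,
                                                 wind_mean = 12, rain = 1),
                               config = fix$config)
  m2 <- assemble_night_metrics(fix$night$audio,
                               covariates = list(roost_size = 300,
                                                 temp_mean = 4,
                                                 wind_mean = 12, rain = 1),
                               config = fix$config)
  expect_identical(m1, m2)
  expect_true(is.na(m1$light_mean))
  expect_identical(m1$roost_size, 300)
  expect_true(m1$night_call_prop_alt <= m1$night_call_prop)
})

test_that("assembly errors carry the failing stage's label", {
  short <- audio_night(numeric(30 * 8000), 8000)
  fix <- synthetic_night_fixture()
  expect_error(assemble_night_metrics(short, config = fix$config),
               "\\[noise_profile\\]|\\[trim\\]")
})

test_that("metrics tables round-trip through CSV", {
  fix <- synthetic_night_fixture()
  m <- assemble_night_metrics(fix$night$audio,
                              covariates = list(roost_size = 300),
                              config = fix$config)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(m, path)
  back <- read_metrics_csv(path)
  expect_equal(back$settle_slope, m$settle_slope, tolerance = 1e-12)
  expect_identical(back$site, m$site)
  expect_identical(back$date, m$date)
  unlink(path)
})
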
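test_that("band PSD localizes a pure tone to its band", {
  fs <- 8000
  tone <- audio_night(sin(2 * pi * 2000 * seq_len(2 * fs) / fs), fs)
  in_band <- band_psd_series(tone, c(1000, 3000))$values
  out_band <- band_psd_series(tone, c(3000, 4000))$values
  expect_true(all(in_band - out_band >= 40))
})

test_that("silent audio sits at the dB floor and short audio errors", {
  silent <- audio_night(numeric(2 * 8000), 8000)
  expect_true(all(band_psd_series(silent, c(1000, 3000))$values == -120))
  expect_error(band_psd_series(audio_night(numeric(100), 8000), c(1000, 3000)),
               "shorter than 1 s")
  expect_error(band_psd_series(silent, c(1000, 5000)), "band")
})

test_that("Welch band power matches direct periodogram summation on noise", {
  an <- white_noise_audio(4, -20, seed = 8)
  welch <- band_psd_series(an, c(1000, 3000))$values
  fs <- an$sample_rate
  direct <- vapply(seq_len(4), function(i) {
    periodogram_band_db(an$samples[((i - 1) * fs + 1):(i * fs)], fs,
                        c(1000, 3000))
  }, numeric(1))
  expect_true(all(abs(welch - direct) < 1))
})

test_that("band power is monotone in band width", {
  an <- white_noise_audio(3, -25, seed = 4)
  narrow <- band_psd_series(an, c(1500, 2500))$values
  wide <- band_psd_series(an, c(1000, 3000))$values
  full <- band_psd_series(an, c(0, 4000))$values
  expect_true(all(narrow <= wide))
  expect_true(all(wide <= full))
})

test_that("noise profile matches the theoretical white-noise spectrum", {
  an <- white_noise_audio(120, -20, seed = 2)
  prof <- build_noise_profile(an, c(0, 120))
  # for white noise of variance s2, each interior Hann-windowed FFT bin is
  # complex Gaussian with E|X| = sqrt(pi/4 * s2 * sum(w^2))
  s2 <- mean(an$samples^2)
  w <- 0.5 * (1 - cos(2 * pi * (0:1023) / 1024))
  expected <- sqrt(pi / 4 * s2 * sum(w^2))
  interior <- prof$magnitude[10:500]
  expect_lt(abs(mean(interior) - expected) / expected, 0.1)
})

test_that("noise profiles are stationary and zero for silence", {
  an <- white_noise_audio(120, -20, seed = 3)
  p1 <- build_noise_profile(an, c(0, 50))
  p2 <- build_noise_profile(an, c(60, 110))
  interior <- 10:500
  expect_lt(max(abs(p1$magnitude[interior] - p2$magnitude[interior]) /
                  p2$magnitude[interior]), 0.35)
  expect_lt(abs(mean(p1$magnitude[interior]) / mean(p2$magnitude[interior]) - 1),
            0.05)
  silent <- audio_night(numeric(30 * 8000), 8000)
  expect_true(all(build_noise_profile(silent, c(0, 30))$magnitude == 0))
  expect_error(build_noise_profile(an, c(115, 130)), "outside")
  expect_error(build_noise_profile(an, c(0, 5)), "at least 10 s")
})

test_that("zero-depth spectral gating is the identity", {
  fix <- synthetic_night_fixture()
  audio <- fix$night$audio
  prof <- build_noise_profile(audio, fix$config$noise_profile_window_s)
  out <- spectral_noise_reduce(audio, prof, reduction_db = 0)
  expect_identical(length(out$samples), length(audio$samples))
  expect_lt(max(abs(out$samples - audio$samples)), 1e-6)
})

test_that("spectral gating removes ~6 dB of noise and spares loud calls", {
  fs <- 8000
  set.seed(21)
  noise <- rnorm(20 * fs)
  noise <- noise * 10^(-40 / 20) / sqrt(mean(noise^2))
  # chirp at +30 dB over the noise, 12.0-12.5 s
  d <- 0.5
  tt <- (0:(d * fs - 1)) / fs
  chirp <- sin(2 * pi * (1200 * tt + 1600 / (2 * d) * tt^2))
  chirp <- chirp * 10^(-10 / 20) / sqrt(mean(chirp^2))
  x <- noise
  idx <- (12 * fs + 1):(12.5 * fs)
  x[idx] <- noise[idx] + chirp
  an <- audio_night(x, fs)
  prof <- build_noise_profile(an, c(0, 10))
  red <- spectral_noise_reduce(an, prof, reduction_db = 6)
  energy_db <- function(v) 10 * log10(mean(v^2))
  # noise-only stretch is attenuated by 6 +/- 1 dB
  drop_noise <- energy_db(an$samples[(14 * fs):(19 * fs)]) -
    energy_db(red$samples[(14 * fs):(19 * fs)])
  expect_gt(drop_noise, 5)
  expect_lt(drop_noise, 7)
  # chirp energy in its band passes within 1 dB
  before <- periodogram_band_db(an$samples[idx], fs, c(1000, 3000))
  after <- periodogram_band_db(red$samples[idx], fs, c(1000, 3000))
  expect_lt(abs(before - after), 1)
})

test_that("gating twice attenuates noise at least as much as gating once", {
  an <- white_noise_audio(20, -40, seed = 6)
  prof <- build_noise_profile(an, c(0, 10))
  once <- spectral_noise_reduce(an, prof)
  twice <- spectral_noise_reduce(once, prof)
  e <- function(a) mean(a$samples[(2 * 8000):(18 * 8000)]^2)
  expect_lte(e(twice), e(once))
})

test_that("occupancy trimming keeps the span between the two peaks", {
  # ramp up then down: trimmed series starts at the head-window peak
  v <- c(seq(-60, -20, length.out = 50), seq(-20.5, -70, length.out = 150))
  ps <- psd_series(v)
  tr <- trim_to_occupancy(ps, head_s = 60, tail_s = 80)
  expect_identical(tr$t0_s, 49) # argmax of first 60 values is index 50
  # constant series: earliest ties on both sides
  cs <- psd_series(rep(-50, 200))
  trc <- trim_to_occupancy(cs, head_s = 60, tail_s = 80)
  expect_identical(trc$t0_s, 0)
  expect_identical(length(trc$values), 121L) # indices 1..(200-80+1)
  expect_error(trim_to_occupancy(psd_series(rep(0, 100)), 60, 80),
               "too short")
})

test_that("trimming lands on planted arrival and departure peaks", {
  set.seed(10)
  n <- 2000
  v <- rnorm(n, -60, 1)
  v[301] <- -10   # arrival peak at t = 300 s
  v[n - 100] <- -5 # departure peak 100 s before the end
  tr <- trim_to_occupancy(psd_series(v), head_s = 600, tail_s = 750)
  expect_identical(tr$t0_s, 300)
  expect_identical(length(tr$values), 1600L)
  expect_identical(tr$values[1], v[301])
})

test_that("normalization is a unit-interval min-max with degenerate zeros", {
  ps <- psd_series(c(-80, -60, -40))
  expect_equal(normalize_night(ps)$values, c(0, 0.5, 1))
  set.seed(5)
  any_ps <- psd_series(rnorm(100))
  np <- normalize_night(any_ps)
  expect_identical(min(np$values), 0)
  expect_identical(max(np$values), 1)
  expect_true(np$normalized)
  expect_true(all(normalize_night(psd_series(rep(-33, 10)))$values == 0))
})

test_that("normalization absorbs recorder-position dB offsets and is idempotent", {
  set.seed(6)
  v <- rnorm(500, -50, 8)
  base <- normalize_night(psd_series(v))
  shifted <- normalize_night(psd_series(v + 12.5))
  expect_equal(base$values, shifted$values, tolerance = 1e-12)
  expect_equal(normalize_night(base)$values, base$values, tolerance = 1e-12)
})

test_that("call seconds outrank call-free seconds in nPSD end to end", {
  fix <- synthetic_night_fixture()
  night <- fix$night
  psd <- band_psd_series(night$audio, fix$scenario$call_band_hz)
  npsd <- normalize_night(psd)
  call_secs <- planted_call_seconds(night$truth)
  call_secs <- call_secs[call_secs <= length(npsd$values)]
  free_secs <- setdiff(seq_along(npsd$values), call_secs)
  expect_gt(median(npsd$values[call_secs]), median(npsd$values[free_secs]))
})

test_that("PSD series survive a CSV round trip", {
  fix <- synthetic_night_fixture()
  psd <- band_psd_series(fix$night$audio, c(1000, 3000))
  path <- tempfile(fileext = ".csv")
  write_psd_csv(psd, path)
  back <- read_psd_csv(path)
  expect_equal(back$values, psd$values, tolerance = 1e-12)
  expect_identical(back$band_hz, psd$band_hz)
  expect_identical(back$normalized, psd$normalized)
  unlink(path)
})

test_that("WAV files round-trip through write and read", {
  an <- white_noise_audio(2, -20, seed = 9)
  path <- tempfile(fileext = ".wav")
  write_wav(an, path)
  back <- read_wav(path)
  expect_identical(back$sample_rate, 8000)
  expect_lt(max(abs(back$samples - an$samples)), 1 / 32767)
  expect_error(read_wav({
    p2 <- tempfile(fileext = ".wav")
    writeLines("not audio", p2)
    p2
  }), "RIFF")
  unlink(path)
})
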
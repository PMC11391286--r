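# Shared fixtures and independent oracles, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# One compressed-time synthetic night (1/120 of the nominal 16 h) with a
# matching configuration, reused across acoustic and metric tests.
synthetic_night_fixture <- function() {
  if (is.null(.fixtures$night)) {
    sc <- compressed_night_scenario(scale = 1 / 120, seed = 42,
                                    night_call_rate = 2)
    .fixtures$scenario <- sc
    .fixtures$night <- simulate_night(sc)
    .fixtures$config <- scale_pipeline_config(pipeline_config(), 1 / 120)
  }
  list(scenario = .fixtures$scenario, night = .fixtures$night,
       config = .fixtures$config)
}

# White-noise audio at a given RMS dB level (full-band at fs = 8000, which
# spans the 0-4000 Hz noise band exactly).
white_noise_audio <- function(dur_s, level_db, fs = 8000, seed = 1,
                              ...) {
  set.seed(seed)
  x <- rnorm(dur_s * fs)
  x <- x * 10^(level_db / 20) / sqrt(mean(x^2))
  audio_night(x, fs, ...)
}

# Direct one-sided periodogram band power of one 1 s frame (the oracle for
# the Welch estimate: no windowing, no segment averaging).
periodogram_band_db <- function(x, fs, band) {
  n <- length(x)
  X <- fft(x)
  p <- Mod(X[1:(n %/% 2 + 1)])^2 / (n * fs)
  p[2:(n %/% 2)] <- 2 * p[2:(n %/% 2)]
  f <- (0:(n %/% 2)) * fs / n
  10 * log10(sum(p[f >= band[1] & f <= band[2]]) * fs / n)
}

# Naive O(n^2) re-implementation of the group-departure rule, used as the
# brute-force oracle: repeatedly seed a cluster with the earliest unassigned
# event and grow it by rescanning every unassigned event for the earliest
# same-direction event within the window of the seed and under the gap from
# the cluster's latest member.
brute_force_clusters <- function(events, window_s = 10, gap_s = 2) {
  events <- events[order(events$time_s), , drop = FALSE]
  n <- nrow(events)
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  while (anyNA(cluster)) {
    cid <- cid + 1L
    seed_i <- which(is.na(cluster))[1]
    cluster[seed_i] <- cid
    first_t <- events$time_s[seed_i]
    last_t <- first_t
    repeat {
      cand <- which(
        is.na(cluster) &
          events$direction == events$direction[seed_i] &
          events$time_s - first_t <= window_s &
          events$time_s - last_t < gap_s
      )
      if (!length(cand)) break
      nxt <- cand[which.min(events$time_s[cand])]
      cluster[nxt] <- cid
      last_t <- events$time_s[nxt]
    }
  }
  cluster
}

# Random event set with enough time collisions to exercise the rule.
random_event_set <- function(n, seed, t_max = 40, n_dirs = 3) {
  set.seed(seed)
  data.frame(
    time_s = sort(round(runif(n, 0, t_max), 2)),
    n_birds = sample(1:3, n, replace = TRUE),
    direction = sample(c("N", "NE", "E", "SE", "S", "SW", "W", "NW")[1:n_dirs],
                       n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Partitions agree up to relabelling of cluster ids.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Seconds (1-based frame index) overlapped by any planted call.
planted_call_seconds <- function(truth) {
  secs <- integer(0)
  for (i in seq_along(truth$call_times_s)) {
    t0 <- truth$call_times_s[i]
    t1 <- t0 + truth$call_durations_s[i]
    secs <- c(secs, seq(floor(t0), floor(t1)) + 1L)
  }
  sort(unique(secs))
}
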
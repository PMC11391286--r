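#' Scenario for a synthetic departure-event stream
#'
#' Plants collective group departures (two or more birds leaving within a
#' short window, in the same direction) and singleton departures at known
#' times, for round-trip testing of the group-segmentation rule.
#'
#' @param roost_size Total number of birds in the roost.
#' @param group_sizes Integer vector: birds per planted group (each >= 2).
#' @param group_start_times_s First-event time of each group, seconds.
#' @param within_group_spread_s Maximum span of a group's events, seconds
#'   (<= 10 to respect the segmentation window).
#' @param inter_group_gap_s Minimum separation between clusters, seconds
#'   (>= 2 to respect the segmentation gap rule).
#' @param directions Optional direction label per group (8-sector compass,
#'   `"N"`, `"NE"`, ...); drawn at random if `NULL`.
#' @param singleton_times_s Times of single-bird departures, seconds.
#' @param seed Integer seed.
#' @return An object of class `event_scenario`.
#' @export
event_scenario <- function(roost_size = 100,
                           group_sizes = integer(0),
                           group_start_times_s = numeric(0),
                           within_group_spread_s = 8,
                           inter_group_gap_s = 4,
                           directions = NULL,
                           singleton_times_s = numeric(0),
                           seed = 1L) {
  if (length(group_sizes) != length(group_start_times_s))
    stop("group_sizes and group_start_times_s must have equal length")
  if (any(group_sizes < 2)) stop("each planted group needs >= 2 birds")
  if (sum(group_sizes) + length(singleton_times_s) > roost_size)
    stop("planted departures exceed roost_size")
  if (within_group_spread_s > 10)
    stop("within_group_spread_s must be <= 10 s")
  if (inter_group_gap_s < 2)
    stop("inter_group_gap_s must be >= 2 s")
  structure(as.list(environment()), class = "event_scenario")
}

COMPASS_8 <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Simulate a departure-event stream with planted group structure
#'
#' Each planted group of size k becomes k single-bird events whose
#' consecutive gaps are drawn below both 2 s and the group's allowed spread,
#' so the planted partition is recoverable by
#' [segment_group_departures()] whenever spreads and gaps respect its
#' thresholds. Errors if planted clusters of the same direction would
#' overlap or violate the inter-group gap.
#'
#' @param scenario An [event_scenario()].
#' @return A list with `events` (a data frame of `time_s`, `n_birds`,
#'   `direction`, sorted by time) and `truth` (the planted cluster id per
#'   event row; singletons get their own ids).
#' @export
simulate_events <- function(scenario) {
  stopifnot(inherits(scenario, "event_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    k <- length(sc$group_sizes)
    dirs <- sc$directions %||%
      sample(COMPASS_8, max(k, 1), replace = TRUE)[seq_len(k)]
    times <- numeric(0)
    direction <- character(0)
    cluster <- integer(0)
    for (g in seq_len(k)) {
      m <- sc$group_sizes[g]
      max_gap <- min(1.9, sc$within_group_spread_s / max(1, m - 1))
      gaps <- stats::runif(m - 1, 0.05, max_gap)
      t_g <- sc$group_start_times_s[g] + c(0, cumsum(gaps))
      times <- c(times, t_g)
      direction <- c(direction, rep(dirs[g], m))
      cluster <- c(cluster, rep(g, m))
    }
    if (length(sc$singleton_times_s)) {
      times <- c(times, sc$singleton_times_s)
      direction <- c(direction,
                     sample(COMPASS_8, length(sc$singleton_times_s),
                            replace = TRUE))
      cluster <- c(cluster, k + seq_along(sc$singleton_times_s))
    }
    ev <- data.frame(time_s = times, n_birds = rep(1L, length(times)),
                     direction = direction, stringsAsFactors = FALSE)
    ord <- order(ev$time_s, ev$direction)
    ev <- ev[ord, , drop = FALSE]
    cluster <- cluster[ord]
    rownames(ev) <- NULL
    # planted clusters of the same direction must be separated by the gap
    for (d in unique(ev$direction)) {
      idx <- which(ev$direction == d)
      for (c1 in unique(cluster[idx])) {
        for (c2 in unique(cluster[idx])) {
          if (c1 >= c2) next
          gap <- min(abs(outer(ev$time_s[idx][cluster[idx] == c1],
                               ev$time_s[idx][cluster[idx] == c2], "-")))
          if (gap < sc$inter_group_gap_s)
            stop("planted groups overlap: clusters ", c1, " and ", c2,
                 " in direction ", d, " are separated by only ",
                 signif(gap, 3), " s")
        }
      }
    }
    list(events = ev, truth = cluster)
  })
}
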
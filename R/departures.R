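#' Validate a table of departure events
#'
#' @param events Data frame with columns `time_s` (seconds, finite),
#'   `n_birds` (integer >= 1) and `direction` (8-sector compass label).
#' @return The validated data frame (sorted by time).
#' @export
departure_events <- function(events) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) {
    return(data.frame(time_s = numeric(0), n_birds = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  req <- c("time_s", "n_birds", "direction")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(events$time_s))) stop("event times must be finite")
  if (any(events$n_birds < 1)) stop("each event needs n_birds >= 1")
  events$direction <- as.character(events$direction)
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Segment departure events into collective group departures
#'
#' Implements the group-departure rule: birds leaving in the same direction
#' belong to one departing cluster while each consecutive gap is shorter
#' than `gap_s` and every event falls within `window_s` of the cluster's
#' first event. Clusters are built greedily left-to-right within each
#' direction (events in different compass sectors never merge). Clusters
#' totalling two or more birds are group departures; single-bird clusters
#' are singletons.
#'
#' @param events Data frame of departure events (see [departure_events()]);
#'   sorted by time if not already.
#' @param window_s Maximum span of a group, anchored at its first event
#'   (default 10 s).
#' @param gap_s Minimum separation between clusters: a new cluster opens
#'   when the gap to the previous same-direction event reaches this value
#'   (default 2 s).
#' @return An object of class `departure_segmentation`: a list with
#'   `events` (the sorted input plus a `cluster` id column), `clusters`
#'   (one row per cluster: start, end, total birds, direction) and `groups`
#'   (the subset of clusters with >= 2 birds).
#' @examples
#' ev <- data.frame(time_s = c(0, 1, 2, 30), n_birds = 1, direction = "N")
#' segment_group_departures(ev)
#' @export
segment_group_departures <- function(events, window_s = 10, gap_s = 2) {
  events <- departure_events(events)
  n <- nrow(events)
  cluster <- integer(n)
  next_id <- 1L
  # per-direction open cluster state
  open <- list()
  for (i in seq_len(n)) {
    d <- events$direction[i]
    t <- events$time_s[i]
    st <- open[[d]]
    if (!is.null(st) &&
        (t - st$last) < gap_s && (t - st$first) <= window_s) {
      cluster[i] <- st$id
      st$last <- t
      open[[d]] <- st
    } else {
      cluster[i] <- next_id
      open[[d]] <- list(id = next_id, first = t, last = t)
      next_id <- next_id + 1L
    }
  }
  events$cluster <- cluster
  clusters <- if (n > 0) {
    agg <- lapply(split(seq_len(n), cluster), function(idx) {
      data.frame(cluster = cluster[idx[1]],
                 start_s = min(events$time_s[idx]),
                 end_s = max(events$time_s[idx]),
                 total_birds = sum(events$n_birds[idx]),
                 n_events = length(idx),
                 direction = events$direction[idx[1]],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$start_s), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(cluster = integer(0), start_s = numeric(0),
               end_s = numeric(0), total_birds = integer(0),
               n_events = integer(0), direction = character(0),
               stringsAsFactors = FALSE)
  }
  structure(
    list(events = events, clusters = clusters,
         groups = clusters[clusters$total_birds >= 2, , drop = FALSE]),
    class = "departure_segmentation"
  )
}

#' @method print departure_segmentation
#' @export
print.departure_segmentation <- function(x, ...) {
  cat(sprintf("<departure_segmentation> %d events, %d clusters, %d groups\n",
              nrow(x$events), nrow(x$clusters), nrow(x$groups)))
  invisible(x)
}

#' Summarise a night's departures
#'
#' Cohesion (the proportion of roost members leaving together in the largest
#' departing group), the number of group departures, and the roost-emptying
#' time (first departure to last departure).
#'
#' @param segmentation A [segment_group_departures()] result.
#' @param roost_size Total number of birds at the roost; must be positive
#'   and at least the number of departing birds observed.
#' @return A one-row data frame: `largest_group_prop`, `n_groups`,
#'   `time_to_empty_s`, `roost_size`.
#' @export
departure_summary <- function(segmentation, roost_size) {
  stopifnot(inherits(segmentation, "departure_segmentation"))
  if (roost_size <= 0) stop("roost_size must be positive")
  total <- sum(segmentation$events$n_birds)
  if (roost_size < total)
    stop(sprintf("roost_size (%g) smaller than departing birds (%g)",
                 roost_size, total))
  groups <- segmentation$groups
  ev <- segmentation$events
  data.frame(
    largest_group_prop =
      if (nrow(groups)) max(groups$total_birds) / roost_size else 0,
    n_groups = nrow(groups),
    time_to_empty_s =
      if (nrow(ev) > 1) max(ev$time_s) - min(ev$time_s) else 0,
    roost_size = roost_size
  )
}

#' Smallest possible group as a percentage of the roost
#'
#' Two birds departing together are the smallest possible group; this is
#' that group expressed as a percentage of roost size, rounded to two
#' decimal places.
#'
#' @param roost_size Roost size in birds (>= 2).
#' @return Percentage, rounded to 2 d.p.
#' @examples
#' smallest_group_percent(92)   # 2.17
#' smallest_group_percent(1473) # 0.14
#' @export
smallest_group_percent <- function(roost_size) {
  if (any(roost_size < 2)) stop("roost_size must be >= 2")
  round(100 * 2 / roost_size, 2)
}

#' Read / write departure-event tables
#'
#' CSV with columns `time_s`, `n_birds`, `direction`.
#'
#' @param path File path.
#' @param events Data frame of events.
#' @return `read_events_csv()` returns a validated events data frame.
#' @export
read_events_csv <- function(path) {
  departure_events(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(departure_events(events), path, row.names = FALSE)
  invisible(path)
}
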
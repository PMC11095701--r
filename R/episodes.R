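#' Merge proximate dyad sightings into interaction episodes
#'
#' For each canonical dyad, sightings are sorted by time and greedily
#' merged while the gap between successive pings is at most `max_gap_s`
#' (a strictly larger gap starts a new episode). An episode starts at its
#' first ping and ends at its last, so a single-ping episode has duration
#' zero. Every input sighting belongs to exactly one episode and ping
#' counts are conserved: `sum(n_pings) == nrow(records)`.
#'
#' @param records Proximity-filtered dyad sightings (`device_a, device_b,
#'   timestamp, rssi`); row order does not matter.
#' @param config An [analysis_config()].
#' @param roster Optional roster; when given, `role_a`/`role_b` are filled
#'   with the roles of the canonical dyad's devices (in canonical order).
#' @return Episode tibble `dyad_a, dyad_b, start, end, duration_min,
#'   n_pings, mean_rssi, location, role_a, role_b`, sorted by dyad then
#'   start; `location` is `"unknown"` until [add_locations()] is applied.
#' @export
sessionize <- function(records, config, roster = NULL) {
  if (nrow(records) == 0L) return(empty_episodes())
  cd <- canonical_dyad(records$device_a, records$device_b)
  x <- tibble::tibble(dyad_a = cd$a, dyad_b = cd$b,
                      timestamp = records$timestamp, rssi = records$rssi)
  x <- x[order(x$dyad_a, x$dyad_b, x$timestamp), ]
  gap <- as.numeric(difftime(x$timestamp, dplyr::lag(x$timestamp),
                             units = "secs"))
  new_dyad <- is.na(gap) | x$dyad_a != dplyr::lag(x$dyad_a) |
    x$dyad_b != dplyr::lag(x$dyad_b)
  new_ep <- new_dyad | gap > config$max_gap_s
  x$ep <- cumsum(new_ep)
  out <- x |>
    dplyr::group_by(.data$ep) |>
    dplyr::summarise(dyad_a = dplyr::first(.data$dyad_a),
                     dyad_b = dplyr::first(.data$dyad_b),
                     start = min(.data$timestamp),
                     end = max(.data$timestamp),
                     n_pings = dplyr::n(),
                     mean_rssi = mean(.data$rssi),
                     .groups = "drop") |>
    dplyr::mutate(duration_min = as.numeric(difftime(.data$end, .data$start,
                                                     units = "mins")),
                  location = "unknown") |>
    dplyr::select("dyad_a", "dyad_b", "start", "end", "duration_min",
                  "n_pings", "mean_rssi", "location")
  attach_roles(out, roster)
}

attach_roles <- function(episodes, roster) {
  if (is.null(roster)) {
    episodes$role_a <- NA_character_
    episodes$role_b <- NA_character_
  } else {
    episodes$role_a <- roster$role[match(episodes$dyad_a, roster$device_id)]
    episodes$role_b <- roster$role[match(episodes$dyad_b, roster$device_id)]
  }
  episodes
}

empty_episodes <- function() {
  tibble::tibble(dyad_a = character(), dyad_b = character(),
                 start = as.POSIXct(character(), tz = "UTC"),
                 end = as.POSIXct(character(), tz = "UTC"),
                 duration_min = numeric(), n_pings = integer(),
                 mean_rssi = numeric(), location = character(),
                 role_a = character(), role_b = character())
}

#' Attribute a location to an interaction episode
#'
#' Returns the modal location marker among the two devices'
#' location-marker pings that fall inside the episode window widened by
#' `max_gap_s` on each side; `"unknown"` when there are none. Ties are
#' broken in favour of the marker observed earliest in the window.
#'
#' @param episode One-row episode tibble (or list) with `dyad_a, dyad_b,
#'   start, end`.
#' @param location_sightings Sightings of `kind == "location"`
#'   (`device_a` = wearable, `device_b` = marker label).
#' @param config An [analysis_config()].
#' @return A single location label.
#' @export
attribute_location <- function(episode, location_sightings, config) {
  gap <- config$max_gap_s
  s <- location_sightings
  sel <- s$device_a %in% c(episode$dyad_a, episode$dyad_b) &
    s$timestamp >= episode$start - gap &
    s$timestamp <= episode$end + gap
  s <- s[sel, ]
  if (nrow(s) == 0L) return("unknown")
  counts <- table(s$device_b)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  first_seen <- vapply(top, function(m) min(as.numeric(s$timestamp[s$device_b == m])),
                       numeric(1))
  top[which.min(first_seen)]
}

#' Attribute locations to every episode in a table
#'
#' Vectorized application of [attribute_location()].
#'
#' @param episodes Episode tibble from [sessionize()].
#' @param location_sightings Location-marker sightings.
#' @param config An [analysis_config()].
#' @return `episodes` with the `location` column filled.
#' @export
add_locations <- function(episodes, location_sightings, config) {
  if (nrow(episodes) == 0L) return(episodes)
  if (is.null(location_sightings) || nrow(location_sightings) == 0L) {
    episodes$location <- "unknown"
    return(episodes)
  }
  episodes$location <- vapply(seq_len(nrow(episodes)), function(i) {
    attribute_location(episodes[i, ], location_sightings, config)
  }, character(1))
  episodes
}

#' Episodes longer than the long-interaction threshold
#'
#' Under the default `"strict"` rule an episode qualifies only when its
#' duration strictly exceeds `long_interaction_min` (so a 2.0-minute
#' episode does not count as "over two minutes"); the `"inclusive"` rule
#' uses greater-or-equal.
#'
#' @param episodes Episode tibble.
#' @param config An [analysis_config()].
#' @return The qualifying subset of `episodes`.
#' @export
long_episodes <- function(episodes, config) {
  if (config$long_rule == "strict") {
    episodes[episodes$duration_min > config$long_interaction_min, ]
  } else {
    episodes[episodes$duration_min >= config$long_interaction_min, ]
  }
}
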
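#' Log-distance RSSI model
#'
#' Received signal strength at a given device separation under the
#' standard log-distance path-loss model:
#' `rssi = rssi_at_1m - 10 * exponent * log10(d)` plus an additive noise
#' term supplied by the caller. Strictly decreasing in distance at zero
#' noise.
#'
#' @param d_m Distance in metres (> 0); vectorized.
#' @param model List with `rssi_at_1m` (dBm) and `exponent`; see
#'   [home_config()].
#' @param noise_db Additive noise draw(s) in dB (default 0).
#' @return RSSI in dBm.
#' @examples
#' rssi_from_distance(1, list(rssi_at_1m = -59, exponent = 2))   # -59
#' rssi_from_distance(10, list(rssi_at_1m = -59, exponent = 2))  # -79
#' @export
rssi_from_distance <- function(d_m, model, noise_db = 0) {
  if (any(!is.finite(d_m)) || any(d_m <= 0)) {
    stop("distance must be a positive, finite number of metres", call. = FALSE)
  }
  model$rssi_at_1m - 10 * model$exponent * log10(d_m) + noise_db
}

hm_to_hours <- function(hm) {
  p <- strsplit(hm, ":", fixed = TRUE)
  vapply(p, function(x) as.numeric(x[1]) + as.numeric(x[2]) / 60, numeric(1))
}

# intersect two sets of [start, end) hour intervals (2-col matrices)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(numeric(0), ncol = 2))
  out <- list()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out[[length(out) + 1L]] <- cbind(lo[keep], hi[keep])
  }
  if (!length(out)) matrix(numeric(0), ncol = 2) else do.call(rbind, out)
}

roles_staffish <- function(role) role %in% c("staff", "agency")

# Piecewise-constant within-day rate multiplier segments for one role pair.
# Returns a data.frame(start_h, end_h, mult) covering the pair's joint
# presence; handover spikes apply to staff(/agency)-staff(/agency) pairs,
# the midday boost to any pair involving staff or agency.
pair_segments <- function(role_a, role_b, cfg) {
  shift <- do.call(rbind, lapply(cfg$shift_windows, function(w) hm_to_hours(w)))
  shift <- matrix(shift, ncol = 2)
  res_day <- matrix(hm_to_hours(cfg$resident_day), ncol = 2)
  win_of <- function(r) if (r == "resident") res_day else shift
  joint <- intersect_intervals(win_of(role_a), win_of(role_b))
  if (nrow(joint) == 0L) {
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      mult = numeric(0)))
  }
  both_staffish <- roles_staffish(role_a) && roles_staffish(role_b)
  any_staffish <- roles_staffish(role_a) || roles_staffish(role_b)

  hand <- matrix(numeric(0), ncol = 2)
  if (both_staffish && cfg$handover_boost != 1) {
    len_h <- cfg$handover_len_min / 60
    hand <- do.call(rbind, apply(shift, 1, function(w) {
      mid <- (w[1] + w[2]) / 2
      rbind(c(w[1], w[1] + len_h),
            c(mid - len_h / 2, mid + len_h / 2),
            c(w[2] - len_h, w[2]))
    }, simplify = FALSE))
  }
  midday <- if (any_staffish && cfg$midday_boost != 1) {
    matrix(c(10, 15), ncol = 2)
  } else matrix(numeric(0), ncol = 2)

  segs <- list()
  for (i in seq_len(nrow(joint))) {
    a <- joint[i, 1]; b <- joint[i, 2]
    brk <- sort(unique(c(a, b,
                         pmin(pmax(c(hand), a), b),
                         pmin(pmax(c(midday), a), b))))
    for (j in seq_len(length(brk) - 1L)) {
      lo <- brk[j]; hi <- brk[j + 1L]
      if (hi <= lo) next
      mid <- (lo + hi) / 2
      m <- 1
      if (nrow(hand) && any(mid >= hand[, 1] & mid < hand[, 2])) {
        m <- m * cfg$handover_boost
      }
      if (nrow(midday) && mid >= midday[1, 1] && mid < midday[1, 2]) {
        m <- m * cfg$midday_boost
      }
      segs[[length(segs) + 1L]] <- data.frame(start_h = lo, end_h = hi,
                                              mult = m)
    }
  }
  do.call(rbind, segs)
}

role_pair_key <- function(r1, r2) {
  paste(pmin(r1, r2), pmax(r1, r2), sep = "-")
}

#' Simulate a care home's BLE sighting stream with known ground truth
#'
#' Generates interaction episodes for every dyad from an inhomogeneous
#' Poisson process whose rate is the configured role-pair base rate times
#' clock-time boosts (handover spikes for staff-staff, a midday boost for
#' staff-involving pairs) and a within-unit multiplier for dyads sharing a
#' planted care unit; staff dyads interact only inside shift windows,
#' residents only during their waking day. Each episode then emits BLE
#' pings at a fixed scan cadence (each scan independently dropped with the
#' configured miss probability), with RSSI from the log-distance model at
#' a per-episode contact distance drawn uniformly from 0.3--1.5 m, plus
#' device-to-location-marker pings for the episode's location. Episodes of
#' the same dyad are kept separated by more than `min_separation_s` so the
#' planted truth is recoverable by sessionization.
#'
#' @param config A [home_config()].
#' @return A list with
#'   \describe{
#'     \item{sightings}{tibble `device_a, device_b, timestamp, rssi, kind`
#'       ordered by time; `kind` is `"dyad"` or `"location"`.}
#'     \item{truth}{a `ground_truth` list: `episodes` (dyad, start, end,
#'       duration, location, roles), `communities` (planted unit per
#'       resident/staff device) and `rates` (per role pair: dyad hours,
#'       expected and realized episode counts).}
#'     \item{roster}{tibble `device_id, role, home, unit`.}
#'   }
#' @examples
#' sim <- simulate_home(home_config(n_residents = 3, n_staff = 2,
#'                                  sim_days = 1, seed = 42))
#' head(sim$sightings)
#' @export
simulate_home <- function(config) {
  cfg <- validate_home_config(config)
  n_people <- cfg$n_residents + cfg$n_staff + cfg$n_agency
  if (n_people == 0L) {
    return(list(sightings = empty_sightings(),
                truth = empty_truth(),
                roster = tibble::tibble(device_id = character(),
                                        role = character(),
                                        home = character(),
                                        unit = integer())))
  }
  if (n_people == 1L) stop("population must contain at least two people or be empty",
                           call. = FALSE)
  set.seed(cfg$seed)

  roster <- roster_ids(cfg)
  units <- rep(NA_integer_, n_people)
  core <- roster$role != "agency"
  if (!is.null(cfg$unit_assignment)) {
    units[core] <- as.integer(cfg$unit_assignment[roster$device_id[core]])
  } else if (cfg$n_units > 0L) {
    units[core] <- rep_len(seq_len(cfg$n_units), sum(core))
  }
  roster$unit <- units
  roster$home <- cfg$home_name
  roster <- roster[, c("device_id", "role", "home", "unit")]

  day0 <- lubridate::ymd(cfg$start_date, tz = "UTC")

  # agency attendance, drawn up front in fixed order
  agency_ids <- roster$device_id[roster$role == "agency"]
  present <- matrix(TRUE, nrow = n_people, ncol = cfg$sim_days,
                    dimnames = list(roster$device_id, NULL))
  if (length(agency_ids)) {
    present[agency_ids, ] <- matrix(
      stats::runif(length(agency_ids) * cfg$sim_days) < cfg$agency_presence_prob,
      nrow = length(agency_ids))
  }

  # dyads in canonical (sorted device id) order
  idx <- utils::combn(order(roster$device_id), 2)
  dy <- tibble::tibble(
    a = roster$device_id[idx[1, ]], b = roster$device_id[idx[2, ]],
    role_a = roster$role[idx[1, ]], role_b = roster$role[idx[2, ]],
    unit_a = roster$unit[idx[1, ]], unit_b = roster$unit[idx[2, ]])
  dy$pair <- role_pair_key(dy$role_a, dy$role_b)
  dy$bias <- ifelse(!is.na(dy$unit_a) & !is.na(dy$unit_b) &
                      dy$unit_a == dy$unit_b, cfg$within_unit_bias, 1)

  seg_by_pair <- lapply(stats::setNames(nm = unique(dy$pair)), function(p) {
    roles <- strsplit(p, "-", fixed = TRUE)[[1]]
    pair_segments(roles[1], roles[2], cfg)
  })
  lam_by_pair <- vapply(names(seg_by_pair), function(p) {
    s <- seg_by_pair[[p]]
    sum((s$end_h - s$start_h) * s$mult) * cfg$rate_matrix[[p]]
  }, numeric(1))
  hours_by_pair <- vapply(seg_by_pair,
                          function(s) sum(s$end_h - s$start_h), numeric(1))

  # expected episodes per dyad-day (before any day both members are absent)
  grid <- tidyr::expand_grid(di = seq_len(nrow(dy)), day = seq_len(cfg$sim_days))
  grid$active <- present[cbind(match(dy$a[grid$di], roster$device_id), grid$day)] &
    present[cbind(match(dy$b[grid$di], roster$device_id), grid$day)]
  grid$lambda <- ifelse(grid$active,
                        lam_by_pair[dy$pair[grid$di]] * dy$bias[grid$di], 0)
  grid$n <- stats::rpois(nrow(grid), grid$lambda)

  eps <- draw_episode_times(grid, dy, seg_by_pair, cfg, day0)
  eps <- assign_locations(eps, cfg)

  # realized / expected rate bookkeeping
  rates <- tibble::tibble(role_pair = names(lam_by_pair)) |>
    dplyr::mutate(
      dyad_hours = vapply(.data$role_pair, function(p) {
        sum(grid$active[dy$pair[grid$di] == p]) * hours_by_pair[[p]]
      }, numeric(1), USE.NAMES = FALSE),
      expected_episodes = vapply(.data$role_pair, function(p) {
        sum(grid$lambda[dy$pair[grid$di] == p])
      }, numeric(1), USE.NAMES = FALSE),
      realized_episodes = vapply(.data$role_pair, function(p) {
        sum(eps$role_pair == p)
      }, numeric(1), USE.NAMES = FALSE),
      realized_rate = ifelse(.data$dyad_hours > 0,
                             .data$realized_episodes / .data$dyad_hours, NA_real_))

  sightings <- emit_sightings(eps, cfg)
  truth <- structure(list(
    episodes = eps[, c("dyad_a", "dyad_b", "role_a", "role_b", "start",
                       "end", "duration_min", "location")],
    communities = tibble::tibble(
      device_id = roster$device_id[core],
      unit = roster$unit[core]),
    rates = rates), class = "ground_truth")
  list(sightings = sightings, truth = truth, roster = roster)
}

# Place the drawn per-dyad-day episode counts in time. Starts are sampled
# from the piecewise-constant rate density, durations from the role-pair
# log-normal; a single forward sweep then pushes any episode that would
# start within min_separation_s of its dyad's previous episode to the
# right (dropping it if pushed past the day's presence window), keeping
# realized counts essentially Poisson while guaranteeing separability.
draw_episode_times <- function(grid, dy, seg_by_pair, cfg, day0) {
  tot <- sum(grid$n)
  if (tot == 0L) {
    return(tibble::tibble(dyad_a = character(), dyad_b = character(),
                          role_a = character(), role_b = character(),
                          role_pair = character(), same_unit = logical(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_min = numeric(), location = character()))
  }
  ri <- rep.int(seq_len(nrow(grid)), grid$n)
  di <- grid$di[ri]
  pair <- dy$pair[di]

  # start hour within day: pick a segment (weighted), then uniform inside
  start_h <- numeric(length(ri))
  for (p in unique(pair)) {
    s <- seg_by_pair[[p]]
    w <- (s$end_h - s$start_h) * s$mult
    sel <- which(pair == p)
    seg <- sample.int(nrow(s), length(sel), replace = TRUE, prob = w)
    start_h[sel] <- s$start_h[seg] +
      stats::runif(length(sel)) * (s$end_h[seg] - s$start_h[seg])
  }
  dm <- cfg$duration_model
  mu_tab <- vapply(dm, function(x) log(x[["median_min"]]), numeric(1))
  sd_tab <- vapply(dm, function(x) x[["sdlog"]], numeric(1))
  mu <- unname(mu_tab[pair])
  sd <- unname(sd_tab[pair])
  dur_s <- round(pmax(stats::rlnorm(length(ri), mu, sd) * 60, 1))

  end_tab <- vapply(seg_by_pair, function(s) max(s$end_h), numeric(1))
  day_end_h <- unname(end_tab[pair])
  ep <- tibble::tibble(
    di = di, day = grid$day[ri], pair = pair,
    start_s = round((grid$day[ri] - 1) * 86400 + start_h * 3600),
    dur_s = dur_s,
    limit_s = (grid$day[ri] - 1) * 86400 + day_end_h * 3600)
  ep <- ep[order(ep$di, ep$start_s), ]

  # forward sweep per dyad: enforce > min_separation_s between episodes
  keep <- logical(nrow(ep))
  start_s <- ep$start_s
  cur_dyad <- -1L; cur_end <- -Inf
  sep <- cfg$min_separation_s
  for (i in seq_len(nrow(ep))) {
    if (ep$di[i] != cur_dyad) { cur_dyad <- ep$di[i]; cur_end <- -Inf }
    s <- start_s[i]
    if (s <= cur_end + sep) s <- cur_end + sep + 1
    if (s > ep$limit_s[i]) next
    start_s[i] <- s
    cur_end <- s + ep$dur_s[i]
    keep[i] <- TRUE
  }
  ep$start_s <- start_s
  ep <- ep[keep, ]

  tibble::tibble(
    dyad_a = dy$a[ep$di], dyad_b = dy$b[ep$di],
    role_a = dy$role_a[ep$di], role_b = dy$role_b[ep$di],
    role_pair = ep$pair,
    same_unit = dy$bias[ep$di] > 1,
    start = day0 + ep$start_s,
    end = day0 + ep$start_s + ep$dur_s,
    duration_min = ep$dur_s / 60,
    location = NA_character_)
}

assign_locations <- function(eps, cfg) {
  if (nrow(eps) == 0L || !length(cfg$locations)) return(eps)
  weight_for <- function(both_staffish) {
    w <- rep(1, length(cfg$locations))
    names(w) <- cfg$locations
    staffy <- grepl("staff|smoking", cfg$locations)
    communal <- grepl("lounge|dining|garden", cfg$locations)
    if (both_staffish && any(staffy)) w[staffy] <- 6
    if (!both_staffish) { w[communal] <- 4; if (any(staffy)) w[staffy] <- 0.2 }
    w / sum(w)
  }
  bs <- roles_staffish(eps$role_a) & roles_staffish(eps$role_b)
  eps$location <- NA_character_
  for (flag in unique(bs)) {
    sel <- which(bs == flag)
    w <- weight_for(flag)
    eps$location[sel] <- sample(cfg$locations, length(sel),
                                replace = TRUE, prob = w)
  }
  eps
}

#' Emit the BLE sighting stream implied by a set of true episodes
#'
#' Exposed separately from [simulate_home()] so that hand-built episode
#' tables can be turned into sightings in tests and examples. Each episode
#' produces dyad pings at exact `ping_interval_s` cadence from start to
#' end inclusive, RSSI from the log-distance model at one contact distance
#' per episode (uniform 0.3--1.5 m) plus Gaussian noise per ping, and
#' device-to-marker pings for the episode's location; every scheduled scan
#' is dropped independently with `ping_miss_prob`. Reported RSSI is
#' rounded to whole dBm, as BLE radios report it.
#'
#' @param episodes Tibble with columns `dyad_a, dyad_b, start, end,
#'   location` (location may be `NA`).
#' @param config A [home_config()] (fields `ping_interval_s`,
#'   `ping_miss_prob`, `rssi_model`, `decoy_rate` are used).
#' @return Sightings tibble `device_a, device_b, timestamp, rssi, kind`.
#' @export
emit_sightings <- function(episodes, config) {
  cfg <- config
  if (nrow(episodes) == 0L) return(empty_sightings())
  int <- cfg$ping_interval_s
  dur_s <- as.numeric(difftime(episodes$end, episodes$start, units = "secs"))
  k <- floor(dur_s / int) + 1L
  ei <- rep.int(seq_len(nrow(episodes)), k)
  off <- (sequence(k) - 1) * int
  t <- episodes$start[ei] + off

  d_contact <- stats::runif(nrow(episodes), 0.3, 1.5)
  noise <- stats::rnorm(length(ei), 0, cfg$rssi_model$noise_sd)
  rssi <- round(rssi_from_distance(d_contact[ei], cfg$rssi_model, noise))
  swap <- stats::runif(length(ei)) < 0.5
  a <- ifelse(swap, episodes$dyad_b[ei], episodes$dyad_a[ei])
  b <- ifelse(swap, episodes$dyad_a[ei], episodes$dyad_b[ei])
  dyad <- tibble::tibble(device_a = a, device_b = b, timestamp = t,
                         rssi = rssi, kind = "dyad")
  keep <- stats::runif(nrow(dyad)) >= cfg$ping_miss_prob
  dyad <- dyad[keep, ]

  loc <- NULL
  has_loc <- !is.na(episodes$location)
  if (any(has_loc)) {
    li <- ei[has_loc[ei]]
    tt <- t[has_loc[ei]]
    d_loc <- stats::runif(nrow(episodes), 0.5, 2.5)   # device-to-marker
    mk <- function(dev) {
      n <- length(li)
      tibble::tibble(device_a = dev,
                     device_b = episodes$location[li],
                     timestamp = tt,
                     rssi = round(rssi_from_distance(
                       d_loc[li], cfg$rssi_model,
                       stats::rnorm(n, 0, cfg$rssi_model$noise_sd))),
                     kind = "location")
    }
    loc <- dplyr::bind_rows(mk(episodes$dyad_a[li]), mk(episodes$dyad_b[li]))
    loc <- loc[stats::runif(nrow(loc)) >= cfg$ping_miss_prob, ]
  }

  decoy <- NULL
  if (cfg$decoy_rate > 0) {
    span_s <- as.numeric(difftime(max(episodes$end), min(episodes$start),
                                  units = "secs"))
    n_dec <- stats::rpois(1, cfg$decoy_rate * span_s / 3600 *
                            length(unique(paste(episodes$dyad_a, episodes$dyad_b))))
    if (n_dec > 0) {
      pick <- sample.int(nrow(episodes), n_dec, replace = TRUE)
      decoy <- tibble::tibble(
        device_a = episodes$dyad_a[pick],
        device_b = episodes$dyad_b[pick],
        timestamp = min(episodes$start) + round(stats::runif(n_dec, 0, span_s)),
        rssi = round(rssi_from_distance(
          stats::runif(n_dec, 3, 8), cfg$rssi_model,
          stats::rnorm(n_dec, 0, cfg$rssi_model$noise_sd))),
        kind = "dyad")
    }
  }

  out <- dplyr::bind_rows(dyad, loc, decoy)
  out[order(out$timestamp, out$device_a, out$device_b), ]
}

empty_sightings <- function() {
  tibble::tibble(device_a = character(), device_b = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 rssi = numeric(), kind = character())
}

empty_truth <- function() {
  structure(list(
    episodes = tibble::tibble(dyad_a = character(), dyad_b = character(),
                              role_a = character(), role_b = character(),
                              start = as.POSIXct(character(), tz = "UTC"),
                              end = as.POSIXct(character(), tz = "UTC"),
                              duration_min = numeric(),
                              location = character()),
    communities = tibble::tibble(device_id = character(), unit = integer()),
    rates = tibble::tibble(role_pair = character(), dyad_hours = numeric(),
                           expected_episodes = numeric(),
                           realized_episodes = numeric(),
                           realized_rate = numeric())),
    class = "ground_truth")
}

fmt_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")

#' Write a simulated sighting stream to the pipeline's CSV dialect
#'
#' Header exactly `device_a,device_b,timestamp,rssi`; timestamps are
#' ISO-8601 with an explicit UTC offset.
#'
#' @param sightings Sightings tibble from [simulate_home()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(sightings, path) {
  out <- tibble::tibble(device_a = sightings$device_a,
                        device_b = sightings$device_b,
                        timestamp = fmt_iso(sightings$timestamp),
                        rssi = sightings$rssi)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a roster to CSV (`device_id,role,home,unit`)
#' @param roster Roster tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster[, c("device_id", "role", "home", "unit")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write / read simulator ground truth
#'
#' The truth round-trips losslessly through three plain CSV files in
#' `dir`: `truth_episodes.csv`, `truth_communities.csv` and
#' `truth_rates.csv`.
#'
#' @param truth A `ground_truth` object from [simulate_home()].
#' @param dir Directory to write into (created if missing).
#' @return `dir` (for `write_truth`); a `ground_truth` (for `read_truth`).
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- truth$episodes
  ep$start <- fmt_iso(ep$start); ep$end <- fmt_iso(ep$end)
  readr::write_csv(ep, file.path(dir, "truth_episodes.csv"), progress = FALSE)
  readr::write_csv(truth$communities, file.path(dir, "truth_communities.csv"),
                   progress = FALSE)
  readr::write_csv(truth$rates, file.path(dir, "truth_rates.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  ep <- readr::read_csv(file.path(dir, "truth_episodes.csv"),
                        col_types = readr::cols(
                          start = readr::col_character(),
                          end = readr::col_character(),
                          duration_min = readr::col_double(),
                          .default = readr::col_character()),
                        progress = FALSE)
  ep$start <- lubridate::ymd_hms(ep$start, tz = "UTC")
  ep$end <- lubridate::ymd_hms(ep$end, tz = "UTC")
  comm <- readr::read_csv(file.path(dir, "truth_communities.csv"),
                          col_types = readr::cols(
                            device_id = readr::col_character(),
                            unit = readr::col_integer()),
                          progress = FALSE)
  rates <- readr::read_csv(file.path(dir, "truth_rates.csv"),
                           col_types = readr::cols(
                             role_pair = readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
  structure(list(episodes = ep, communities = comm, rates = rates),
            class = "ground_truth")
}
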
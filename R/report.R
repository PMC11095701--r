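q_lin <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)

#' Median and IQR of tie strength and episode duration, per home
#'
#' Medians and interquartile ranges (Q3 - Q1, linear-interpolation
#' quantiles) of edge weights -- relationship strength as episode counts
#' -- and of episode durations in minutes, grouped by home. Homes present
#' in the network but without episodes get a row of `NA`s rather than
#' being dropped.
#'
#' @param net Contact network.
#' @param episodes Episode tibble.
#' @param roster Roster tibble (supplies the home of each device).
#' @return Tibble `home, weight_median, weight_iqr, duration_median_min,
#'   duration_iqr_min`.
#' @export
strength_duration_summary <- function(net, episodes, roster) {
  homes <- sort(unique(roster$home))
  el <- igraph::as_edgelist(net)
  ew <- igraph::E(net)$weight
  edge_home <- roster$home[match(el[, 1], roster$device_id)]
  ep_home <- roster$home[match(episodes$dyad_a, roster$device_id)]
  purrr::map_dfr(homes, function(h) {
    w <- ew[edge_home == h]
    d <- episodes$duration_min[ep_home == h]
    tibble::tibble(
      home = h,
      weight_median = if (length(w)) q_lin(w, 0.5) else NA_real_,
      weight_iqr = if (length(w)) q_lin(w, 0.75) - q_lin(w, 0.25) else NA_real_,
      duration_median_min = if (length(d)) q_lin(d, 0.5) else NA_real_,
      duration_iqr_min = if (length(d)) q_lin(d, 0.75) - q_lin(d, 0.25) else NA_real_)
  })
}

#' Degree and weighted degree by home and role
#'
#' Per (home, role) group: head count, mean, and 5th / 95th percentiles
#' (linear interpolation) of degree and weighted degree. Every home is
#' reported for all three roles; an absent role gives an `n = 0` row.
#'
#' @param net Contact network (nodes carry `home` and `role`).
#' @return Tibble with one row per home x role.
#' @export
centrality_by_role <- function(net) {
  k <- degree_centrality(net)
  s <- weighted_degree(net)
  nodes <- tibble::tibble(home = igraph::V(net)$home,
                          role = igraph::V(net)$role, k = k, s = s)
  grid <- tidyr::expand_grid(home = sort(unique(nodes$home)),
                             role = c("agency", "resident", "staff"))
  grid |>
    dplyr::left_join(nodes |>
                       dplyr::group_by(.data$home, .data$role) |>
                       dplyr::summarise(
                         n = dplyr::n(),
                         degree_mean = mean(.data$k),
                         degree_p5 = q_lin(.data$k, 0.05),
                         degree_p95 = q_lin(.data$k, 0.95),
                         wdegree_mean = mean(.data$s),
                         wdegree_p5 = q_lin(.data$s, 0.05),
                         wdegree_p95 = q_lin(.data$s, 0.95),
                         .groups = "drop"),
                     by = c("home", "role")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Role-pair contingency of long interactions
#'
#' Cross-tabulates long episodes by the ordered role pair
#' `(role_a, role_b)` of the canonical dyad (rows = first role, columns =
#' second), with row totals, column totals, a grand total, and each
#' column total as a percentage of the grand total rounded to one
#' decimal. `collapse = TRUE` merges the symmetric cells
#' `(r1, r2)` and `(r2, r1)` into the upper triangle.
#'
#' @param long_eps Long-episode tibble (see [long_episodes()]) with
#'   `role_a` and `role_b` columns.
#' @param collapse Merge symmetric role pairs (default `FALSE`).
#' @return List with `counts` (3x3 matrix), `row_totals`, `col_totals`,
#'   `grand_total` and `col_pct` (1 dp, sums to 100 up to rounding).
#' @export
role_contingency <- function(long_eps, collapse = FALSE) {
  lv <- c("agency", "resident", "staff")
  ra <- factor(long_eps$role_a, levels = lv)
  rb <- factor(long_eps$role_b, levels = lv)
  counts <- table(ra, rb)
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(lv, lv))
  if (collapse) {
    low <- lower.tri(counts)
    counts[t(low)] <- counts[t(low)] + t(counts)[t(low)]
    counts[low] <- 0L
  }
  grand <- sum(counts)
  col_tot <- colSums(counts)
  list(counts = counts,
       row_totals = rowSums(counts),
       col_totals = col_tot,
       grand_total = grand,
       col_pct = if (grand > 0) round(100 * col_tot / grand, 1)
                 else stats::setNames(rep(0, 3), lv))
}

#' Unique contact partners versus total interactions, by role
#'
#' For each person: the number of distinct partners ("unique
#' interactions") and the total episode count; per role: head count,
#' means and SDs of both, and mean unique as a percentage of mean total.
#' Every rostered person counts, including those with no episodes.
#'
#' @param episodes Episode tibble.
#' @param roster Roster tibble.
#' @return Tibble `role, n_individuals, unique_mean, unique_sd,
#'   unique_pct_of_all, total_mean, total_sd`.
#' @export
unique_interactions <- function(episodes, roster) {
  both <- dplyr::bind_rows(
    tibble::tibble(person = episodes$dyad_a, partner = episodes$dyad_b),
    tibble::tibble(person = episodes$dyad_b, partner = episodes$dyad_a))
  per_person <- both |>
    dplyr::group_by(.data$person) |>
    dplyr::summarise(unique_partners = dplyr::n_distinct(.data$partner),
                     total_interactions = dplyr::n(), .groups = "drop")
  people <- roster |>
    dplyr::left_join(per_person, by = c(device_id = "person")) |>
    dplyr::mutate(unique_partners = dplyr::coalesce(.data$unique_partners, 0L),
                  total_interactions = dplyr::coalesce(.data$total_interactions, 0L))
  people |>
    dplyr::group_by(role = .data$role) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      unique_mean = mean(.data$unique_partners),
      unique_sd = stats::sd(.data$unique_partners),
      total_mean = mean(.data$total_interactions),
      total_sd = stats::sd(.data$total_interactions),
      .groups = "drop") |>
    dplyr::mutate(unique_pct_of_all = ifelse(.data$total_mean > 0,
                                             100 * .data$unique_mean / .data$total_mean,
                                             0)) |>
    dplyr::select("role", "n_individuals", "unique_mean", "unique_sd",
                  "unique_pct_of_all", "total_mean", "total_sd")
}

collapse_pair <- function(role_a, role_b) {
  # three-category view: agency folds into staff
  a <- ifelse(role_a == "agency", "staff", role_a)
  b <- ifelse(role_b == "agency", "staff", role_b)
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Hour-of-day interaction heat map data
#'
#' Counts each episode in every `[t, t + bin)` clock-hour bin it
#' overlaps, per calendar date and collapsed role-pair class (res-res,
#' res-staff, staff-staff; agency folds into staff for this
#' three-category view). Clock time is rendered in the report time zone.
#'
#' @param episodes Episode tibble with roles attached.
#' @param config An [analysis_config()] (`hour_bin_h`, `report_tz`).
#' @return Tibble `date, hour, pair, n` (one row per non-empty cell).
#' @export
temporal_heatmap <- function(episodes, config) {
  if (config$hour_bin_h <= 0) stop("bin width must be positive", call. = FALSE)
  if (nrow(episodes) == 0L) {
    return(tibble::tibble(date = as.Date(character()), hour = numeric(),
                          pair = character(), n = integer()))
  }
  bin_s <- config$hour_bin_h * 3600
  lo <- floor(as.numeric(episodes$start) / bin_s)
  hi <- floor(as.numeric(episodes$end) / bin_s)
  idx <- rep.int(seq_len(nrow(episodes)), hi - lo + 1L)
  bins <- (sequence(hi - lo + 1L) - 1L) + lo[idx]
  t_bin <- as.POSIXct(bins * bin_s, origin = "1970-01-01", tz = "UTC")
  local <- lubridate::with_tz(t_bin, config$report_tz)
  tibble::tibble(date = as.Date(local, tz = config$report_tz),
                 hour = lubridate::hour(local) + lubridate::minute(local) / 60,
                 pair = collapse_pair(episodes$role_a[idx],
                                      episodes$role_b[idx])) |>
    dplyr::count(.data$date, .data$hour, .data$pair, name = "n")
}

#' Episode counts per attributed location
#'
#' @param episodes Episode tibble (with `location`, `"unknown"` allowed).
#' @return Tibble `location, n`, most frequent first.
#' @export
location_frequency <- function(episodes) {
  if (nrow(episodes) == 0L) {
    return(tibble::tibble(location = character(), n = integer()))
  }
  episodes |>
    dplyr::count(location = .data$location, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$location)
}

#' Rank community members by connectedness
#'
#' Sorts nodes by weighted degree (descending), breaking ties by degree
#' and then device ID, and flags the least-connected bottom decile
#' (weighted degree at or below the 10th percentile).
#'
#' @param net Contact network.
#' @return Tibble `rank, device_id, role, home, weighted_degree, degree,
#'   least_connected`.
#' @export
connectedness_ranking <- function(net) {
  s <- weighted_degree(net)
  k <- degree_centrality(net)
  out <- tibble::tibble(device_id = igraph::V(net)$name,
                        role = igraph::V(net)$role,
                        home = igraph::V(net)$home,
                        weighted_degree = as.numeric(s),
                        degree = as.numeric(k)) |>
    dplyr::arrange(dplyr::desc(.data$weighted_degree),
                   dplyr::desc(.data$degree), .data$device_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  cutoff <- q_lin(out$weighted_degree, 0.10)
  out$least_connected <- out$weighted_degree <= cutoff
  out
}
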
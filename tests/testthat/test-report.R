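test_that("strength/duration summary handles single values, quantile rule and empty homes", {
  roster <- tiny_roster(c("A", "B", "C"), c("resident", "staff", "resident"))
  ep <- episode_row("A", "B", "2022-01-01 10:00:00", 8)
  one <- build_network(ep, roster)
  s <- strength_duration_summary(one, ep, roster)
  expect_equal(s$weight_median, 1)
  expect_equal(s$duration_median_min, 8)
  expect_equal(s$weight_iqr, 0)

  # weights 1,2,3,4 under linear-interpolation quantiles
  eps4 <- dplyr::bind_rows(
    lapply(1:4, function(w) {
      dplyr::bind_rows(lapply(seq_len(w), function(k) {
        episode_row(LETTERS[w], LETTERS[w + 10],
                    as.POSIXct("2022-01-01 08:00:00", tz = "UTC") + k * 7200, 5)
      }))
    }))
  roster4 <- tiny_roster(c(LETTERS[1:4], LETTERS[11:14]),
                         rep(c("resident", "staff"), each = 4))
  net4 <- build_network(eps4, roster4)
  s4 <- strength_duration_summary(net4, eps4, roster4)
  expect_equal(s4$weight_median, 2.5)
  expect_equal(s4$weight_iqr, unname(quantile(1:4, 0.75) - quantile(1:4, 0.25)))

  # a home with no episodes appears as an NA row, not an omission
  roster2 <- dplyr::bind_rows(roster, tiny_roster("Z", "resident", home = "H2"))
  s2 <- strength_duration_summary(build_network(ep, roster2), ep, roster2)
  expect_equal(nrow(s2), 2L)
  expect_true(is.na(s2$weight_median[s2$home == "H2"]))
})

test_that("centrality by role reports all roles with percentile columns", {
  roster <- tiny_roster(c("A", "B", "C", "D"),
                        c("resident", "resident", "staff", "staff"))
  eps <- dplyr::bind_rows(
    episode_row("A", "C", "2022-01-01 10:00:00", 5),
    episode_row("B", "D", "2022-01-01 10:00:00", 5),
    episode_row("A", "D", "2022-01-01 12:00:00", 5),
    episode_row("B", "C", "2022-01-01 12:00:00", 5))
  net <- build_network(eps, roster)
  cb <- centrality_by_role(net)
  expect_equal(nrow(cb), 3L)   # one home x three roles
  res <- cb[cb$role == "resident", ]
  expect_equal(res$degree_mean, 2)          # all nodes have degree 2
  expect_equal(res$degree_p5, 2)
  expect_equal(res$degree_p95, 2)
  expect_equal(cb$n[cb$role == "agency"], 0L)
})

test_that("role contingency reproduces printed-table arithmetic", {
  # a reference table of long-interaction counts by role pair, rebuilt as episodes
  cells <- expand.grid(role_a = c("agency", "resident", "staff"),
                       role_b = c("agency", "resident", "staff"),
                       stringsAsFactors = FALSE)
  cells$n <- c(1, 5, 23, 14, 493, 1061, 24, 972, 2300)
  eps <- cells[rep(seq_len(nrow(cells)), cells$n), c("role_a", "role_b")]
  eps <- tibble::as_tibble(eps)
  eps$duration_min <- 3
  ct <- role_contingency(eps)
  expect_equal(ct$grand_total, 4893)
  expect_equal(unname(ct$col_totals), c(29, 1568, 3296))
  expect_equal(unname(ct$row_totals), c(39, 1470, 3384))
  expect_equal(unname(ct$col_pct), c(0.6, 32.0, 67.4))
})

test_that("role contingency degenerate and rounding properties hold", {
  one <- tibble::tibble(role_a = "staff", role_b = "staff",
                        duration_min = 5)
  ct <- role_contingency(one)
  expect_equal(unname(ct$col_pct), c(0, 0, 100.0))
  empty <- role_contingency(one[0, ])
  expect_equal(empty$grand_total, 0)
  set.seed(51)
  for (i in 1:10) {
    eps <- tibble::tibble(
      role_a = sample(c("agency", "resident", "staff"), 200, TRUE),
      role_b = sample(c("agency", "resident", "staff"), 200, TRUE))
    ct <- role_contingency(eps)
    expect_lt(abs(sum(ct$col_pct) - 100), 0.1 + 1e-9)
    expect_equal(ct$grand_total, 200)
  }
})

test_that("symmetric collapse merges mirrored role pairs", {
  eps <- tibble::tibble(role_a = c("resident", "staff"),
                        role_b = c("staff", "resident"))
  ct <- role_contingency(eps, collapse = TRUE)
  expect_equal(ct$counts["resident", "staff"], 2L)
  expect_equal(ct$counts["staff", "resident"], 0L)
  expect_equal(ct$grand_total, 2)
})

test_that("unique-partner summary counts distinct partners per person", {
  roster <- tiny_roster(c("A", "B", "C"), c("resident", "staff", "staff"))
  eps <- dplyr::bind_rows(
    episode_row("A", "B", "2022-01-01 10:00:00", 5),
    episode_row("A", "B", "2022-01-01 12:00:00", 5),
    episode_row("A", "B", "2022-01-01 14:00:00", 5))
  u <- unique_interactions(eps, roster)
  res <- u[u$role == "resident", ]
  expect_equal(res$unique_mean, 1)
  expect_equal(res$total_mean, 3)
  expect_equal(res$unique_pct_of_all, 100 / 3, tolerance = 1e-9)
  staff <- u[u$role == "staff", ]
  expect_equal(staff$n_individuals, 2L)    # C has zero interactions
  expect_equal(staff$unique_mean, 0.5)
  zero <- unique_interactions(eps[0, ], roster)
  expect_true(all(zero$total_mean == 0))
})

test_that("temporal heat map bins overlapped hours and spans midnight", {
  cfg <- analysis_config(report_tz = "UTC")
  one <- episode_row("A", "B", "2022-01-01 10:00:00", 30,
                     role_a = "resident", role_b = "staff")
  hm <- temporal_heatmap(one, cfg)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$hour, 10)
  expect_equal(hm$pair, "resident-staff")

  night <- episode_row("A", "B", "2022-01-01 23:50:00", 20,
                       role_a = "staff", role_b = "staff")
  hm2 <- temporal_heatmap(night, cfg)
  expect_equal(hm2$date, as.Date(c("2022-01-01", "2022-01-02")))
  expect_equal(hm2$hour, c(23, 0))

  # agency folds into staff in the three-category view
  ag <- episode_row("A", "B", "2022-01-01 09:00:00", 5,
                    role_a = "agency", role_b = "resident")
  expect_equal(temporal_heatmap(ag, cfg)$pair, "resident-staff")
})

test_that("a configured midday boost is visible in realized truth", {
  cfg <- home_config(n_residents = 6, n_staff = 8, sim_days = 21,
                     handover_boost = 1, midday_boost = 2.5,
                     within_unit_bias = 1, n_units = 0, seed = 52)
  sim <- simulate_home(cfg)
  ep <- sim$truth$episodes
  staffish <- ep[ep$role_a != "resident" | ep$role_b != "resident", ]
  hr <- lubridate::hour(staffish$start) + lubridate::minute(staffish$start) / 60
  mid_rate <- sum(hr >= 10 & hr < 15) / 5
  edge_rate <- sum((hr >= 8 & hr < 10) | (hr >= 15 & hr < 20)) / 7
  expect_gt(mid_rate, edge_rate)
})

test_that("location frequency tallies episodes including unknowns", {
  eps <- dplyr::bind_rows(
    episode_row("A", "B", "2022-01-01 10:00:00", 5, location = "lounge"),
    episode_row("A", "B", "2022-01-01 12:00:00", 5, location = "lounge"),
    episode_row("A", "B", "2022-01-01 14:00:00", 5, location = "staff-room"))
  lf <- location_frequency(eps)
  expect_equal(lf$n[lf$location == "lounge"], 2L)
  eps$location <- "unknown"
  expect_equal(location_frequency(eps)$location, "unknown")
})

test_that("connectedness ranking orders by strength and flags the bottom decile", {
  roster <- tiny_roster(sprintf("P%02d", 1:5), rep("resident", 5))
  eps <- dplyr::bind_rows(lapply(2:5, function(i) {
    dplyr::bind_rows(lapply(seq_len(i), function(k) {
      episode_row("P01", sprintf("P%02d", i),
                  as.POSIXct("2022-01-01 08:00:00", tz = "UTC") + k * 7200, 5)
    }))
  }))
  net <- build_network(eps, roster)
  rk <- connectedness_ranking(net)
  expect_equal(rk$device_id[1], "P01")
  expect_true(rk$least_connected[rk$device_id == "P02"])
  isolated <- build_network(empty_episodes(), roster)
  expect_true(all(connectedness_ranking(isolated)$least_connected))
})

test_that("the pipeline reproduces planted truth and is byte-deterministic", {
  cfg <- home_config(n_residents = 4, n_staff = 4, sim_days = 2,
                     ping_miss_prob = 0,
                     rssi_model = list(rssi_at_1m = -66, exponent = 4,
                                       noise_sd = 0), seed = 53)
  sim <- simulate_home(cfg)
  sfile <- tempfile(fileext = ".csv"); rfile <- tempfile(fileext = ".csv")
  write_sightings(sim$sightings, sfile)
  write_roster(sim$roster, rfile)
  acfg <- analysis_config(report_tz = "UTC")
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- run_pipeline(sfile, rfile, out_dir = d1, config = acfg)
  b2 <- run_pipeline(sfile, rfile, out_dir = d2, config = acfg)
  expect_equal(nrow(b1$episodes), nrow(sim$truth$episodes))
  # per-home medians recompute from the planted episodes
  truth_median <- median(floor(as.numeric(difftime(
    sim$truth$episodes$end, sim$truth$episodes$start, units = "secs")) /
      cfg$ping_interval_s) * cfg$ping_interval_s / 60)
  expect_equal(b1$strength_duration$duration_median_min, truth_median)
  # truth locations are recovered through marker pings (aligned on start)
  joined <- dplyr::inner_join(
    b1$episodes[, c("dyad_a", "dyad_b", "start", "location")],
    sim$truth$episodes[, c("dyad_a", "dyad_b", "start", "location")],
    by = c("dyad_a", "dyad_b", "start"), suffix = c("_got", "_true"))
  expect_equal(nrow(joined), nrow(sim$truth$episodes))
  expect_gte(mean(joined$location_got == joined$location_true), 0.95)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("an empty input produces an empty but valid bundle", {
  sfile <- tempfile(fileext = ".csv")
  writeLines("device_a,device_b,timestamp,rssi", sfile)
  rfile <- tempfile(fileext = ".csv")
  writeLines(c("device_id,role,home,unit", "R1,resident,H,1",
               "S1,staff,H,1"), rfile)
  b <- run_pipeline(sfile, rfile, config = analysis_config())
  expect_equal(nrow(b$episodes), 0L)
  expect_equal(b$network_summary$n_nodes, 2L)
  expect_equal(b$network_summary$n_edges, 0L)
  expect_equal(b$role_contingency$grand_total, 0)
  expect_equal(nrow(b$rankings), 2L)
})
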
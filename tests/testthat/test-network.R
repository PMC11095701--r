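star_net <- function() {
  make_net(data.frame(i = 1, j = 2:5, weight = 1), 5)
}

test_that("network construction keeps isolates and counts episodes as weights", {
  roster <- tiny_roster(c("A", "B", "C"), c("resident", "staff", "resident"))
  empty <- build_network(empty_episodes(), roster)
  expect_equal(igraph::vcount(empty), 3L)
  expect_equal(igraph::ecount(empty), 0L)

  eps <- dplyr::bind_rows(
    episode_row("A", "B", "2022-01-01 10:00:00", 5),
    episode_row("A", "B", "2022-01-01 12:00:00", 3),
    episode_row("A", "B", "2022-01-01 14:00:00", 1))
  net <- build_network(eps, roster)
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$weight, 3)
  expect_equal(igraph::E(net)$total_minutes, 9)

  bad <- episode_row("A", "Z", "2022-01-01 10:00:00", 5)
  expect_error(build_network(bad, roster), "Z")
})

test_that("edge weights equal planted episode counts at zero miss probability", {
  cfg <- home_config(n_residents = 4, n_staff = 4, sim_days = 2,
                     ping_miss_prob = 0,
                     rssi_model = list(rssi_at_1m = -66, exponent = 4,
                                       noise_sd = 0), seed = 14)
  sim <- simulate_home(cfg)
  acfg <- analysis_config()
  dyad <- filter_proximate(sim$sightings[sim$sightings$kind == "dyad", ], acfg)
  ep <- sessionize(dyad, acfg, sim$roster)
  net <- build_network(ep, sim$roster)
  truth_w <- table(paste(sim$truth$episodes$dyad_a,
                         sim$truth$episodes$dyad_b))
  el <- igraph::as_edgelist(net)
  got <- stats::setNames(igraph::E(net)$weight, paste(el[, 1], el[, 2]))
  expect_equal(sort(names(got)), sort(names(truth_w)))
  expect_equal(as.numeric(got[names(truth_w)]), as.numeric(truth_w))
})

test_that("degree obeys star/isolate examples and the handshake identity", {
  st <- star_net()
  expect_equal(unname(degree_centrality(st)), c(4, 1, 1, 1, 1))
  iso <- make_net(data.frame(i = 1, j = 2, weight = 1), 3)
  expect_equal(unname(degree_centrality(iso))[3], 0)
  set.seed(2)
  for (i in 1:10) {
    g <- random_net(8, 0.4)
    expect_equal(sum(degree_centrality(g)), 2 * igraph::ecount(g))
  }
})

test_that("weighted degree sums incident weights and collapses to degree at unit weight", {
  g <- make_net(data.frame(i = 1, j = 2, weight = 79), 2)
  expect_equal(unname(weighted_degree(g)), c(79, 79))
  set.seed(3)
  g <- random_net(7, 0.5, weighted = FALSE)
  expect_equal(weighted_degree(g), degree_centrality(g))
  g <- random_net(7, 0.6, weighted = TRUE)
  A <- net_adjacency(g, weighted = TRUE)
  expect_equal(unname(weighted_degree(g)), rowSums(A))
})

test_that("closeness matches its textbook forms and the Floyd-Warshall oracle", {
  path3 <- make_net(data.frame(i = c(1, 2), j = c(2, 3), weight = 1), 3)
  expect_equal(unname(closeness_centrality(path3, "classic"))[2], 1.0)
  iso <- make_net(data.frame(i = 1, j = 2, weight = 1), 3)
  expect_equal(unname(closeness_centrality(iso))[3], 0)
  set.seed(5)
  for (i in 1:20) {
    g <- random_net(6, runif(1, 0.2, 0.8))
    expect_equal(unname(closeness_centrality(g, "harmonic")),
                 bf_harmonic_closeness(g), tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(g, "classic")),
                 bf_classic_closeness(g), tolerance = 1e-12)
  }
})

test_that("betweenness matches path enumeration on canonical and random graphs", {
  path3 <- make_net(data.frame(i = c(1, 2), j = c(2, 3), weight = 1), 3)
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  k4 <- make_net(data.frame(t(utils::combn(4, 2)) |>
                              `colnames<-`(c("i", "j")), weight = 1), 4)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  set.seed(6)
  for (i in 1:15) {
    g <- random_net(7, runif(1, 0.25, 0.7))
    expect_equal(unname(betweenness_centrality(g)), bf_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality is the L2-normalized principal eigenvector", {
  k4 <- make_net(data.frame(t(utils::combn(4, 2)) |>
                              `colnames<-`(c("i", "j")), weight = 1), 4)
  ev <- eigenvector_centrality(k4)
  expect_equal(unname(ev), rep(0.5, 4), tolerance = 1e-8)
  st <- star_net()
  evs <- eigenvector_centrality(st)
  expect_true(evs[1] > max(evs[-1]))
  set.seed(8)
  for (i in 1:10) {
    g <- random_net(5, 0.8)
    A <- net_adjacency(g, weighted = TRUE)
    ref <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    expect_equal(unname(eigenvector_centrality(g)), ref, tolerance = 1e-6)
  }
  none <- make_net(data.frame(i = integer(), j = integer(),
                              weight = numeric()), 3)
  expect_error(eigenvector_centrality(none), "edgeless")
})

test_that("density spans complete, empty and the 50-node regime of a cohesive home", {
  k4 <- make_net(data.frame(t(utils::combn(4, 2)) |>
                              `colnames<-`(c("i", "j")), weight = 1), 4)
  expect_equal(network_density(k4), 1)
  none <- make_net(data.frame(i = integer(), j = integer(),
                              weight = numeric()), 4)
  expect_equal(network_density(none), 0)
  # 699 edges over 50 nodes: density 2*699/(50*49) = 0.5706...
  set.seed(9)
  pairs <- t(utils::combn(50, 2))
  pick <- pairs[sample(nrow(pairs), 699), ]
  g <- make_net(data.frame(i = pick[, 1], j = pick[, 2], weight = 1), 50)
  expect_equal(network_density(g), 2 * 699 / (50 * 49))
  expect_equal(round(network_density(g), 2), 0.57)
})

test_that("clustering coefficient matches triangle enumeration", {
  tri <- make_net(data.frame(i = c(1, 1, 2), j = c(2, 3, 3), weight = 1), 3)
  expect_equal(unname(clustering_coefficient(tri)$local), rep(1, 3))
  st <- star_net()
  expect_equal(unname(clustering_coefficient(st)$local)[1], 0)
  set.seed(10)
  for (i in 1:10) {
    g <- random_net(7, 0.5)
    A <- net_adjacency(g)
    k <- rowSums(A)
    tri_n <- diag(A %*% A %*% A) / 2
    ref <- ifelse(k < 2, 0, 2 * tri_n / (k * (k - 1)))
    expect_equal(unname(clustering_coefficient(g)$local), ref,
                 tolerance = 1e-12)
  }
})

test_that("Freeman centralization is 1 for a star, 0 for regular graphs", {
  expect_equal(degree_centralization(star_net()), 1)
  ring <- make_net(data.frame(i = 1:6, j = c(2:6, 1), weight = 1), 6)
  expect_equal(degree_centralization(ring), 0)
  set.seed(11)
  g <- random_net(6, 0.5)
  k <- degree_centrality(g)
  expect_equal(degree_centralization(g), sum(max(k) - k) / (5 * 4))
})

test_that("role assortativity reflects within-role versus cross-role mixing", {
  within <- make_net(data.frame(i = c(1, 3), j = c(2, 4), weight = 1), 4,
                     roles = c("staff", "staff", "resident", "resident"))
  expect_equal(role_assortativity(within), 1)
  across <- make_net(data.frame(i = c(1, 2), j = c(3, 4), weight = 1), 4,
                     roles = c("staff", "staff", "resident", "resident"))
  expect_lt(role_assortativity(across), 0)
  # hand-computed mixing-matrix trace formula on a mixed fixture
  g <- make_net(data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4), weight = 1),
                4, roles = c("staff", "staff", "resident", "resident"))
  types <- c(1, 1, 2, 2)
  el <- igraph::as_edgelist(g, names = FALSE)
  E <- matrix(0, 2, 2)
  for (e in seq_len(nrow(el))) {
    a <- types[el[e, 1]]; b <- types[el[e, 2]]
    E[a, b] <- E[a, b] + 1; E[b, a] <- E[b, a] + 1
  }
  E <- E / sum(E)
  ai <- rowSums(E)
  ref <- (sum(diag(E)) - sum(ai^2)) / (1 - sum(ai^2))
  expect_equal(role_assortativity(g), ref, tolerance = 1e-12)
})

test_that("all centralities are invariant under node relabelling", {
  set.seed(12)
  g <- random_net(8, 0.5)
  perm <- sample(8)
  g2 <- igraph::permute(g, perm)
  reorder <- function(x) x[igraph::V(g)$name]
  expect_equal(reorder(degree_centrality(g2)), degree_centrality(g))
  expect_equal(reorder(weighted_degree(g2)), weighted_degree(g))
  expect_equal(reorder(closeness_centrality(g2)), closeness_centrality(g))
  expect_equal(reorder(betweenness_centrality(g2)),
               betweenness_centrality(g))
  if (igraph::ecount(g) > 0) {
    expect_equal(reorder(eigenvector_centrality(g2)),
                 eigenvector_centrality(g), tolerance = 1e-6)
  }
})

test_that("reciprocity is refused with a clear undirected-data error", {
  expect_error(reciprocity_contact(star_net()), "undirected")
})

test_that("time-windowed networks assign episodes to every overlapped bin", {
  roster <- tiny_roster(c("A", "B"), c("resident", "staff"))
  ep <- episode_row("A", "B", "2022-01-01 09:58:00", 5)
  nets <- time_windowed_networks(ep, roster, bin_s = 3600)
  with_edge <- names(nets)[vapply(nets, igraph::ecount, numeric(1)) > 0]
  expect_equal(with_edge, c("2022-01-01T09:00:00+0000",
                            "2022-01-01T10:00:00+0000"))
  expect_equal(time_windowed_networks(empty_episodes(), roster), list())
  expect_error(time_windowed_networks(ep, roster, bin_s = 0), "positive")
})

test_that("network exports carry attributes readable by standard tools", {
  roster <- tiny_roster(c("A", "B", "C"), c("resident", "staff", "agency"))
  ep <- episode_row("A", "B", "2022-01-01 10:00:00", 5)
  net <- build_network(ep, roster)
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("A", "B", "C"))
  expect_equal(igraph::E(back)$weight, 1)
  gexf <- tempfile(fileext = ".gexf")
  write_network_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 3L)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), 1L)
})
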
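# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# build a contact-network-shaped igraph from an edge data frame
make_net <- function(edges, n, roles = NULL, home = "H") {
  ids <- sprintf("N%02d", seq_len(n))
  if (is.null(roles)) roles <- rep("resident", n)
  verts <- data.frame(name = ids, role = roles, home = home,
                      unit = NA_character_)
  if (nrow(edges)) {
    edges$dyad_a <- ids[edges$i]
    edges$dyad_b <- ids[edges$j]
    edges <- edges[, c("dyad_a", "dyad_b", "weight")]
    edges$total_minutes <- edges$weight
    edges$n_pings <- edges$weight
    edges$mean_rssi <- -70
  } else {
    edges <- data.frame(dyad_a = character(), dyad_b = character(),
                        weight = numeric(), total_minutes = numeric(),
                        n_pings = numeric(), mean_rssi = numeric())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

random_net <- function(n, p = 0.5, weighted = TRUE) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  e <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
  e$weight <- if (weighted && nrow(e)) sample(1:9, nrow(e), TRUE) else
    rep(1, nrow(e))
  make_net(e, n)
}

net_adjacency <- function(net, weighted = FALSE) {
  n <- igraph::vcount(net)
  A <- matrix(0, n, n)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if (weighted) igraph::E(net)$weight else rep(1, nrow(el))
  for (e in seq_len(nrow(el))) {
    A[el[e, 1], el[e, 2]] <- A[el[e, 1], el[e, 2]] + w[e]
    A[el[e, 2], el[e, 1]] <- A[el[e, 2], el[e, 1]] + w[e]
  }
  A
}

# Floyd-Warshall hop distances
bf_distances <- function(net) {
  A <- net_adjacency(net)
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_harmonic_closeness <- function(net) {
  d <- bf_distances(net)
  n <- nrow(d)
  if (n <= 1) return(rep(0, n))
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  })
}

bf_classic_closeness <- function(net) {
  d <- bf_distances(net)
  n <- nrow(d)
  sapply(seq_len(n), function(i) {
    tot <- sum(d[i, -i])
    if (is.finite(tot) && tot > 0) (n - 1) / tot else 0
  })
}

# exhaustive simple-path enumeration betweenness (unordered pairs,
# even split over equally short paths)
bf_betweenness <- function(net) {
  A <- net_adjacency(net)
  n <- nrow(A)
  score <- rep(0, n)
  paths_between <- function(s, t) {
    out <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return() }
      for (u in which(A[v, ] > 0)) if (!u %in% path) dfs(c(path, u))
    }
    dfs(s)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, integer(1))
    sp <- ps[lens == min(lens)]
    for (p in sp) {
      inner <- p[-c(1, length(p))]
      score[inner] <- score[inner] + 1 / length(sp)
    }
  }
  score
}

# direct double-sum modularity
bf_modularity <- function(net, memb, gamma = 1) {
  A <- net_adjacency(net, weighted = TRUE)
  if (sum(A) == 0) return(0)
  k <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) q <- q + A[i, j] - gamma * k[i] * k[j] / m2
  }
  q / m2
}

# all set partitions of n elements as membership vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_label) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return() }
    for (lab in seq_len(next_label)) {
      rec(c(memb, lab), max(next_label, lab + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

bf_best_modularity <- function(net, gamma = 1) {
  parts <- all_partitions(igraph::vcount(net))
  max(vapply(parts, function(p) bf_modularity(net, p, gamma), numeric(1)))
}

# naive per-dyad gap scan sessionizer (plain loops, no vectorization)
bf_sessionize <- function(records, max_gap_s) {
  key <- paste(pmin(records$device_a, records$device_b),
               pmax(records$device_a, records$device_b), sep = "|")
  out <- list()
  for (dk in sort(unique(key))) {
    tt <- sort(as.numeric(records$timestamp[key == dk]))
    start <- tt[1]; prev <- tt[1]; np <- 1L
    for (t in tt[-1]) {
      if (t - prev > max_gap_s) {
        out[[length(out) + 1L]] <- data.frame(dyad = dk, start = start,
                                              end = prev, n_pings = np)
        start <- t; np <- 0L
      }
      prev <- t; np <- np + 1L
    }
    out[[length(out) + 1L]] <- data.frame(dyad = dk, start = start,
                                          end = prev, n_pings = np)
  }
  df <- do.call(rbind, out)
  df[order(df$dyad, df$start), ]
}

# quick builders -----------------------------------------------------------

tiny_roster <- function(ids, roles, home = "H") {
  tibble::tibble(device_id = ids, role = roles, home = home,
                 unit = NA_integer_)
}

episode_row <- function(a, b, start, dur_min, role_a = "resident",
                        role_b = "resident", location = "unknown") {
  start <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(dyad_a = a, dyad_b = b, start = start,
                 end = start + dur_min * 60, duration_min = dur_min,
                 n_pings = max(1L, as.integer(dur_min)), mean_rssi = -70,
                 location = location, role_a = role_a, role_b = role_b)
}

sighting_row <- function(a, b, t, rssi, kind = "dyad") {
  tibble::tibble(device_a = a, device_b = b,
                 timestamp = as.POSIXct(t, tz = "UTC"), rssi = rssi,
                 kind = kind)
}
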
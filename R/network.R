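#' Build a weighted undirected contact network from episodes
#'
#' One node per rostered device (isolated people are kept as degree-0
#' nodes, carrying `role`, `home` and `unit` attributes) and one edge per
#' dyad with at least one episode overlapping the analysis window. The
#' edge weight `w` is the number of such episodes (tie strength as
#' contact frequency); `total_minutes` sums each episode's minutes of
#' overlap with the window, `n_pings` the ping counts and `mean_rssi` the
#' mean of episode mean RSSIs.
#'
#' @param episodes Episode tibble from [sessionize()].
#' @param roster Roster tibble; every device appearing in `episodes` must
#'   be rostered (missing devices are a hard error listing the IDs).
#' @param window Optional `c(start, end)` POSIXct pair; episodes overlap
#'   the half-open window `[start, end)`. Default: all episodes.
#' @return An `igraph` contact network with graph attributes
#'   `window_start` / `window_end`.
#' @export
build_network <- function(episodes, roster, window = NULL) {
  missing <- setdiff(unique(c(episodes$dyad_a, episodes$dyad_b)),
                     roster$device_id)
  if (length(missing)) {
    stop("episodes mention devices absent from the roster: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(window)) {
    window <- if (nrow(episodes)) c(min(episodes$start), max(episodes$end) + 1)
              else as.POSIXct(c(0, 0), origin = "1970-01-01", tz = "UTC")
  }
  keep <- episodes$start < window[2] & episodes$end >= window[1]
  ep <- episodes[keep, , drop = FALSE]
  if (nrow(ep)) {
    ov_start <- pmax(ep$start, window[1])
    ov_end <- pmin(ep$end, window[2])
    ep$ov_min <- pmax(as.numeric(difftime(ov_end, ov_start, units = "mins")), 0)
  }
  edges <- if (nrow(ep)) {
    ep |>
      dplyr::group_by(.data$dyad_a, .data$dyad_b) |>
      dplyr::summarise(weight = dplyr::n(),
                       total_minutes = sum(.data$ov_min),
                       n_pings = sum(.data$n_pings),
                       mean_rssi = mean(.data$mean_rssi),
                       .groups = "drop")
  } else {
    tibble::tibble(dyad_a = character(), dyad_b = character(),
                   weight = integer(), total_minutes = numeric(),
                   n_pings = integer(), mean_rssi = numeric())
  }
  verts <- tibble::tibble(name = roster$device_id, role = roster$role,
                          home = roster$home,
                          unit = as.character(roster$unit))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "window_start", fmt_iso(window[1]))
  igraph::set_graph_attr(g, "window_end", fmt_iso(window[2]))
}

#' Node degree: number of distinct contact partners
#'
#' Raw (unnormalized) counts; the handshake identity
#' `sum(degree) == 2 * ecount` holds on every contact network.
#'
#' @param net Contact network from [build_network()].
#' @return Named numeric vector.
#' @export
degree_centrality <- function(net) igraph::degree(net, loops = FALSE)

#' Weighted degree (strength): summed incident edge weights
#' @inheritParams degree_centrality
#' @return Named numeric vector; equals degree when all weights are 1.
#' @export
weighted_degree <- function(net) {
  s <- igraph::strength(net, weights = igraph::E(net)$weight)
  if (igraph::ecount(net) == 0L) s[] <- 0
  s
}

#' Closeness centrality over unweighted hop distances
#'
#' Default is harmonic closeness -- the mean of reciprocal shortest-path
#' distances to all other nodes, with unreachable nodes contributing 0 --
#' which stays well defined on the disconnected networks that sparsely
#' present agency staff produce. The classic form `(n-1) / sum(d)` is
#' available for connected graphs. Path lengths are unweighted hop
#' counts: edge weights encode tie strength, not distance. Setting
#' `use_weights = TRUE` instead treats `1/weight` as an edge length.
#'
#' @inheritParams degree_centrality
#' @param method `"harmonic"` (default) or `"classic"`.
#' @param use_weights Use inverse edge weight as distance (default FALSE).
#' @return Named numeric vector (0 for a single-node or edgeless graph).
#' @export
closeness_centrality <- function(net, method = c("harmonic", "classic"),
                                 use_weights = FALSE) {
  method <- match.arg(method)
  n <- igraph::vcount(net)
  w <- if (use_weights) 1 / igraph::E(net)$weight else NA
  if (n <= 1L) return(stats::setNames(rep(0, n), igraph::V(net)$name))
  if (method == "harmonic") {
    igraph::harmonic_centrality(net, weights = w, normalized = TRUE)
  } else {
    d <- igraph::distances(net, weights = w)
    diag(d) <- 0
    tot <- rowSums(d)
    out <- ifelse(is.finite(tot) & tot > 0, (n - 1) / tot, 0)
    stats::setNames(out, igraph::V(net)$name)
  }
}

#' Betweenness centrality over unweighted shortest paths
#'
#' Unnormalized pair counts with even splitting over equally short paths
#' (Brandes accumulation); each unordered pair is counted once.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, weights = NA, directed = FALSE)
}

#' Eigenvector centrality of the weighted adjacency
#'
#' Principal eigenvector by power iteration (tolerance 1e-9), returned
#' with non-negative entries and unit L2 norm. Undefined -- an error --
#' on an edgeless graph.
#'
#' @inheritParams degree_centrality
#' @param tol Convergence tolerance on the L2 change per iteration.
#' @param max_iter Iteration cap.
#' @return Named numeric vector with `sum(x^2) == 1`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-9, max_iter = 10000L) {
  if (igraph::ecount(net) == 0L) {
    stop("eigenvector centrality is undefined on an edgeless network",
         call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE)
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  # positive diagonal shift: breaks the +/-lambda tie on bipartite graphs
  # without changing eigenvectors
  shift <- 0.1 * max(igraph::strength(net, weights = igraph::E(net)$weight))
  for (i in seq_len(max_iter)) {
    u <- as.numeric(A %*% v) + shift * v
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    if (sqrt(sum((u - v)^2)) < tol) { v <- u; break }
    v <- u
  }
  stats::setNames(abs(v), igraph::V(net)$name)
}

#' Network density
#'
#' `2E / (N (N - 1))` -- the ratio of edges present to the maximum
#' possible; defined as 0 for networks with fewer than two nodes.
#'
#' @inheritParams degree_centrality
#' @return A single number in `[0, 1]`.
#' @export
network_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) return(0)
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Local clustering coefficient and its mean
#'
#' Unweighted: `2 * triangles / (k (k - 1))` per node, 0 for nodes with
#' fewer than two neighbours.
#'
#' @inheritParams degree_centrality
#' @return List with `local` (named vector) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  local <- igraph::transitivity(net, type = "localundirected",
                                isolates = "zero")
  local[is.na(local)] <- 0
  local <- stats::setNames(local, igraph::V(net)$name)
  list(local = local, mean = mean(local))
}

#' Freeman degree centralization
#'
#' `sum(k_max - k_i) / ((N - 1) (N - 2))`: 1 for a star, 0 for any
#' regular graph; defined as 0 for networks with fewer than three nodes.
#'
#' @inheritParams degree_centrality
#' @return A single number in `[0, 1]`.
#' @export
degree_centralization <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3L) return(0)
  k <- degree_centrality(net)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Categorical assortativity on the role attribute
#'
#' Newman's assortativity coefficient on the role mixing matrix:
#' 1 when edges only join same-role nodes, negative for disassortative
#' (e.g. purely staff-resident) mixing.
#'
#' @inheritParams degree_centrality
#' @return A single number in `[-1, 1]` (`NaN` on degenerate networks).
#' @export
role_assortativity <- function(net) {
  igraph::assortativity_nominal(net,
                                as.integer(factor(igraph::V(net)$role)))
}

#' Reciprocity is not defined for these networks
#'
#' BLE proximity data are symmetric: a sighting of B by A is the same
#' contact as a sighting of A by B, so the contact networks built here
#' are undirected and tie reciprocity cannot be measured. This stub
#' exists so directed-input callers get a clear error rather than a
#' silent wrong answer.
#'
#' @inheritParams degree_centrality
#' @export
reciprocity_contact <- function(net) {
  stop("reciprocity requires directed relationship data; BLE proximity ",
       "contact networks are undirected, so it is not computable here",
       call. = FALSE)
}

#' Contact networks over consecutive time bins
#'
#' Splits the analysis period into half-open bins `[t, t + bin)` aligned
#' to whole bins since midnight of the first episode's day and builds one
#' contact network per bin; an episode contributes to every bin it
#' overlaps.
#'
#' @param episodes Episode tibble.
#' @param roster Roster tibble.
#' @param bin_s Bin width in seconds (> 0).
#' @return Named list of contact networks (names are bin start times);
#'   empty list for no episodes.
#' @export
time_windowed_networks <- function(episodes, roster, bin_s = 3600) {
  if (bin_s <= 0) stop("bin width must be positive", call. = FALSE)
  if (nrow(episodes) == 0L) return(list())
  t0 <- lubridate::floor_date(min(episodes$start), "day")
  first <- floor(as.numeric(difftime(min(episodes$start), t0, units = "secs")) / bin_s)
  last <- floor(as.numeric(difftime(max(episodes$end), t0, units = "secs")) / bin_s)
  out <- list()
  for (b in first:last) {
    lo <- t0 + b * bin_s
    hi <- t0 + (b + 1) * bin_s
    out[[fmt_iso(lo)]] <- build_network(episodes, roster, window = c(lo, hi))
  }
  out
}

#' Export a contact network for external visualisation
#'
#' `write_network_graphml()` writes GraphML; `write_network_gexf()`
#' writes GEXF 1.3 (the Gephi interchange format) with node attributes
#' `role`, `home`, `unit` and `community` (when present) and edge
#' attributes `weight` and `total_minutes`.
#'
#' @param net Contact network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_gexf <- function(net, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.3",
                            version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  node_attrs <- intersect(c("role", "home", "unit", "community"),
                          igraph::vertex_attr_names(net))
  for (i in seq_along(node_attrs)) {
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                        title = node_attrs[i], type = "string")
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(net)$name
  for (v in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[v],
                              label = vnames[v])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (i in seq_along(node_attrs)) {
      val <- igraph::vertex_attr(net, node_attrs[i])[v]
      xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                          value = ifelse(is.na(val), "", as.character(val)))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    w <- igraph::E(net)$weight
    tm <- igraph::E(net)$total_minutes
    for (e in seq_len(nrow(el))) {
      ed <- xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                                source = el[e, 1], target = el[e, 2],
                                weight = as.character(w[e]))
      av <- xml2::xml_add_child(ed, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "total_minutes",
                          value = as.character(tm[e]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
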
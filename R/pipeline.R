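#' Run the full contact-network pipeline
#'
#' Ingest -> proximity filter -> sessionization -> location attribution ->
#' contact network -> node and network metrics -> Louvain subcommunities
#' -> report tables, written as plain CSV/JSON plus GraphML/GEXF network
#' exports and a run manifest (input checksums, row counts, reject counts
#' and the thresholds used). The run is fully deterministic: identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param sightings_path Path to the sightings CSV
#'   (`device_a,device_b,timestamp,rssi`).
#' @param roster_path Path to the roster CSV (`device_id,role,home,unit`).
#' @param out_dir Output directory (created if missing); set `NULL` to
#'   skip writing files.
#' @param config An [analysis_config()].
#' @return A list of class `"report_bundle"`: `episodes`, `long_episodes`,
#'   `network`, `partition`, `node_metrics`, `network_summary`,
#'   `strength_duration`, `centrality_by_role`, `role_contingency`,
#'   `unique_interactions`, `temporal`, `locations`, `rankings`,
#'   `rejects`, `manifest`.
#' @export
run_pipeline <- function(sightings_path, roster_path, out_dir = NULL,
                         config = analysis_config()) {
  roster <- read_roster(roster_path)
  rs <- read_sightings(sightings_path, roster)
  filtered <- filter_proximate(rs$sightings, config)
  dyad <- filtered[is.na(filtered$kind) | filtered$kind == "dyad", ]
  locs <- filtered[!is.na(filtered$kind) & filtered$kind == "location", ]

  episodes <- sessionize(dyad, config, roster)
  episodes <- add_locations(episodes, locs, config)
  longs <- long_episodes(episodes, config)

  net <- build_network(episodes, roster)
  part <- louvain_partition(net)
  net <- igraph::set_vertex_attr(net, "community",
                                 value = as.character(
                                   part$membership[igraph::V(net)$name]))

  k <- degree_centrality(net)
  s <- weighted_degree(net)
  cl <- clustering_coefficient(net)
  eig <- if (igraph::ecount(net) > 0L) eigenvector_centrality(net) else k * NA_real_
  node_metrics <- tibble::tibble(
    device_id = igraph::V(net)$name,
    role = igraph::V(net)$role,
    home = igraph::V(net)$home,
    degree = as.numeric(k),
    weighted_degree = as.numeric(s),
    closeness_harmonic = as.numeric(closeness_centrality(net)),
    betweenness = as.numeric(betweenness_centrality(net)),
    eigenvector = as.numeric(eig),
    clustering = as.numeric(cl$local),
    community = as.integer(part$membership[igraph::V(net)$name]))
  network_summary <- tibble::tibble(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    n_pings_kept = nrow(dyad),
    n_episodes = nrow(episodes),
    n_long_episodes = nrow(longs),
    density = network_density(net),
    degree_centralization = degree_centralization(net),
    role_assortativity = role_assortativity(net),
    mean_clustering = cl$mean,
    modularity_Q = part$Q,
    n_communities = part$n_communities)

  contingency <- role_contingency(longs)
  bundle <- structure(list(
    episodes = episodes,
    long_episodes = longs,
    network = net,
    partition = part,
    node_metrics = node_metrics,
    network_summary = network_summary,
    strength_duration = strength_duration_summary(net, episodes, roster),
    centrality_by_role = centrality_by_role(net),
    role_contingency = contingency,
    unique_interactions = unique_interactions(episodes, roster),
    temporal = temporal_heatmap(episodes, config),
    locations = location_frequency(episodes),
    rankings = connectedness_ranking(net),
    rejects = rs$rejects,
    manifest = run_manifest(sightings_path, roster_path, rs, episodes,
                            longs, config)), class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

run_manifest <- function(sightings_path, roster_path, rs, episodes, longs,
                         config) {
  list(
    inputs = list(
      sightings = basename(sightings_path),
      sightings_md5 = unname(tools::md5sum(sightings_path)),
      roster = basename(roster_path),
      roster_md5 = unname(tools::md5sum(roster_path))),
    rows = list(read = nrow(rs$sightings) + nrow(rs$rejects),
                kept = nrow(rs$sightings),
                rejected = nrow(rs$rejects),
                episodes = nrow(episodes),
                long_episodes = nrow(longs)),
    config = unclass(config))
}

#' Write a report bundle to disk
#'
#' One CSV per table analogue, a JSON bundle, GraphML/GEXF network
#' exports, the rejects report and the run manifest.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ep <- bundle$episodes
  ep$start <- fmt_iso(ep$start); ep$end <- fmt_iso(ep$end)
  readr::write_csv(ep, p("episodes.csv"), progress = FALSE)
  readr::write_csv(bundle$node_metrics, p("node_metrics.csv"), progress = FALSE)
  readr::write_csv(bundle$network_summary, p("network_summary.csv"), progress = FALSE)
  readr::write_csv(bundle$strength_duration, p("strength_duration.csv"), progress = FALSE)
  readr::write_csv(bundle$centrality_by_role, p("centrality_by_role.csv"), progress = FALSE)
  cont <- bundle$role_contingency
  cont_df <- tibble::as_tibble(cont$counts, rownames = "role_a")
  cont_df$row_total <- unname(cont$row_totals)
  readr::write_csv(cont_df, p("role_contingency.csv"), progress = FALSE)
  readr::write_csv(bundle$unique_interactions, p("unique_interactions.csv"), progress = FALSE)
  readr::write_csv(bundle$temporal, p("temporal_heatmap.csv"), progress = FALSE)
  readr::write_csv(bundle$locations, p("location_frequency.csv"), progress = FALSE)
  readr::write_csv(bundle$rankings, p("connectedness_ranking.csv"), progress = FALSE)
  readr::write_csv(bundle$rejects, p("rejects.csv"), progress = FALSE)
  write_network_graphml(bundle$network, p("network.graphml"))
  write_network_gexf(bundle$network, p("network.gexf"))
  json <- list(
    network_summary = bundle$network_summary,
    role_contingency = list(counts = cont$counts,
                            row_totals = cont$row_totals,
                            col_totals = cont$col_totals,
                            grand_total = cont$grand_total,
                            col_pct = cont$col_pct),
    partition = list(Q = bundle$partition$Q,
                     n_communities = bundle$partition$n_communities,
                     membership = as.list(bundle$partition$membership),
                     community_density = bundle$partition$community_density),
    manifest = bundle$manifest)
  jsonlite::write_json(json, p("bundle.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  ns <- x$network_summary
  cat(sprintf(paste0(
    "Contact-network report bundle\n",
    "  people: %d   edges: %d   density: %.3f\n",
    "  proximate pings: %d   episodes: %d   long (>threshold): %d\n",
    "  modularity Q: %.3f in %d subcommunities\n"),
    ns$n_nodes, ns$n_edges, ns$density, ns$n_pings_kept, ns$n_episodes,
    ns$n_long_episodes, ns$modularity_Q, ns$n_communities))
  invisible(x)
}
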
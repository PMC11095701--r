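#' Weighted modularity of a node partition
#'
#' Direct evaluation of `Q = sum_c [ w_in_c / m - gamma (s_c / 2m)^2 ]`
#' where `m` is the total edge weight, `w_in_c` the weight inside
#' community `c` and `s_c` its summed node strength: the fraction of tie
#' strength falling within communities minus its expectation under a
#' strength-preserving random rewiring.
#'
#' @param net Contact network from [build_network()] (edge attribute
#'   `weight`).
#' @param membership Community labels, one per node (any atomic type).
#' @param resolution Resolution parameter `gamma` (default 1).
#' @return Modularity `Q` (0 for an edgeless network).
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  n <- igraph::vcount(net)
  if (length(membership) != n) {
    stop("membership must label every node", call. = FALSE)
  }
  if (igraph::ecount(net) == 0L) return(0)
  memb <- as.integer(factor(membership))
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  m <- sum(w)
  s <- igraph::strength(net, weights = w)
  w_in <- sum(w[memb[el[, 1]] == memb[el[, 2]]])
  s_c <- tapply(s, memb, sum)
  w_in / m - resolution * sum((s_c / (2 * m))^2)
}

# one level of local moves on a dense weight matrix (diag = 2 * internal
# self-weight); returns the membership vector once no move improves Q.
# Gains are evaluated with the node removed from its community, for every
# community holding a neighbour plus the node's own; the largest gain
# wins, ties toward the smallest community label.
louvain_local_moves <- function(W, resolution, init = seq_len(nrow(W))) {
  n <- nrow(W)
  memb <- init
  s <- rowSums(W)
  m <- sum(W) / 2
  sigma <- numeric(max(memb))
  for (i in seq_len(n)) sigma[memb[i]] <- sigma[memb[i]] + s[i]
  repeat {
    moved <- 0L
    for (i in seq_len(n)) {
      a <- memb[i]
      wrow <- W[i, ]
      wrow[i] <- 0
      nb <- which(wrow > 0)
      cand <- unique(c(a, memb[nb]))
      ki <- vapply(cand, function(cc) sum(wrow[memb == cc]), numeric(1))
      sigma[a] <- sigma[a] - s[i]
      gain <- ki / m - resolution * sigma[cand] * s[i] / (2 * m^2)
      best_gain <- max(gain)
      best <- min(cand[gain == best_gain])
      gain_a <- gain[match(a, cand)]
      if (best != a && best_gain - gain_a > 1e-12) {
        memb[i] <- best
        sigma[best] <- sigma[best] + s[i]
        moved <- moved + 1L
      } else {
        sigma[a] <- sigma[a] + s[i]
      }
    }
    if (moved == 0L) break
  }
  memb
}

# full two-phase Louvain on a weight matrix, optionally initialized from
# an existing partition at the first level; returns membership per row
louvain_run <- function(W, resolution, init = seq_len(nrow(W))) {
  memb <- seq_len(nrow(W))
  first <- TRUE
  repeat {
    level <- louvain_local_moves(W, resolution,
                                 init = if (first) init else seq_len(nrow(W)))
    first <- FALSE
    k <- length(unique(level))
    if (k == nrow(W)) break
    relab <- match(level, unique(level))
    memb <- relab[memb]
    W <- rowsum(t(rowsum(W, relab, reorder = FALSE)), relab, reorder = FALSE)
    dimnames(W) <- NULL
  }
  match(memb, unique(memb))
}

#' Louvain subcommunity detection
#'
#' Two-phase Louvain on weighted modularity: repeated single-node moves
#' to the neighbouring community with the largest modularity gain (ties
#' broken toward the smallest community label), followed by aggregation
#' of communities into supernodes, until no move improves Q by more than
#' 1e-12. Because greedy local moves can lodge in scan-order-dependent
#' local optima, the search is repeated from a fixed set of deterministic
#' scan orders -- sorted device ID, its reverse, increasing and
#' decreasing strength, and a few permutations drawn from a private RNG
#' seeded with `seed` -- each followed by a refinement pass that restarts
#' the local moves from the found partition; the best-Q partition wins.
#' The whole procedure is a pure function of the network, `resolution`
#' and `seed` (default 1), so repeated calls are identical. The returned
#' Q is never below the all-singletons baseline. On an edgeless network
#' every node is its own community with Q = 0 by convention.
#'
#' @param net Contact network from [build_network()].
#' @param resolution Resolution parameter `gamma` (default 1).
#' @param seed Integer seed for the extra deterministic scan orders.
#' @return An object of class `"community_partition"`: list with
#'   `membership` (named integer vector, labels 1..K by first
#'   appearance), `Q`, `n_communities`, `community_density` (tibble
#'   `community, size, density` using induced-subgraph density, 0 for
#'   singleton communities) and `resolution`.
#' @export
louvain_partition <- function(net, resolution = 1, seed = 1L) {
  n <- igraph::vcount(net)
  vnames <- igraph::V(net)$name
  ord <- order(vnames)
  if (igraph::ecount(net) == 0L) {
    memb <- stats::setNames(seq_len(n), vnames)
    return(new_partition(net, memb, 0, resolution))
  }
  W0 <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight",
                                              sparse = TRUE))
  W0 <- W0[ord, ord, drop = FALSE] # base scan order: sorted device id
  s <- rowSums(W0)
  orders <- list(seq_len(n), rev(seq_len(n)),
                 order(s, seq_len(n)), order(-s, seq_len(n)))
  draws <- with_private_rng(seed %||% 1L, list(
    orders = lapply(1:4, function(i) sample.int(n)),
    inits = lapply(1:16, function(i) {
      k <- sample(2:min(n, 5), 1)
      sample.int(k, n, replace = TRUE)
    })))
  orders <- c(orders, draws$orders)
  best_q <- -Inf
  best <- NULL
  for (p in orders) {
    lev <- louvain_run(W0[p, p, drop = FALSE], resolution)
    cand <- integer(n)
    cand[p] <- lev
    cand <- louvain_run(W0, resolution, init = cand) # refinement pass
    q <- modularity_matrix_q(W0, cand, resolution)
    if (q > best_q + 1e-12) { best_q <- q; best <- cand }
  }
  # restarts from coarse random partitions reach optima that greedy
  # growth from singletons cannot
  for (init in draws$inits) {
    cand <- louvain_run(W0, resolution, init = match(init, unique(init)))
    q <- modularity_matrix_q(W0, cand, resolution)
    if (q > best_q + 1e-12) { best_q <- q; best <- cand }
  }
  # escape compound-move local optima: tentatively merge each pair of
  # communities, refine with local moves, keep any improvement
  repeat {
    improved <- FALSE
    labs <- unique(best)
    if (length(labs) < 2L) break
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        cand <- best
        cand[cand == labs[j]] <- labs[i]
        cand <- louvain_run(W0, resolution, init = match(cand, unique(cand)))
        q <- modularity_matrix_q(W0, cand, resolution)
        if (q > best_q + 1e-12) {
          best_q <- q; best <- cand; improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  labels <- match(best, unique(best))
  out <- integer(n)
  out[ord] <- labels
  memb_named <- stats::setNames(match(out, unique(out)), vnames)
  q <- modularity_q(net, memb_named, resolution)
  new_partition(net, memb_named, q, resolution)
}

modularity_matrix_q <- function(W, memb, resolution) {
  m <- sum(W) / 2
  s <- rowSums(W)
  same <- outer(memb, memb, "==")
  (sum(W[same]) / 2) / m -
    resolution * sum(tapply(s, memb, sum)^2) / (4 * m^2)
}

# run code with a private RNG stream, leaving the caller's untouched
with_private_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_partition <- function(net, membership, q, resolution) {
  dens <- vapply(unique(membership), function(cc) {
    ids <- names(membership)[membership == cc]
    if (length(ids) < 2L) return(0)
    sub <- igraph::induced_subgraph(net, ids)
    2 * igraph::ecount(sub) / (length(ids) * (length(ids) - 1))
  }, numeric(1))
  structure(list(
    membership = membership,
    Q = q,
    n_communities = length(unique(membership)),
    community_density = tibble::tibble(
      community = unique(membership),
      size = as.integer(table(membership)[as.character(unique(membership))]),
      density = dens),
    resolution = resolution), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, Q = %.4f (resolution %g)\n",
              x$n_communities, x$Q, x$resolution))
  print(x$community_density)
  invisible(x)
}
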
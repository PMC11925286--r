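#' Generate a Watts-Strogatz small-world contact network
#'
#' Builds the shared contact structure used by both the opinion-diffusion and
#' the disease stage: a ring lattice on `n` nodes in which every node is
#' connected to its `k/2` nearest neighbours on either side, with each edge
#' endpoint rewired uniformly at random with probability `p`. Rewiring
#' preserves the edge count, so the result always has exactly `n * k / 2`
#' edges, no self-loops and no duplicate edges.
#'
#' @param n Population size (number of nodes). Must exceed `k`.
#' @param k Mean degree of the base lattice; an even integer of at least 2.
#' @param p Rewiring probability in `[0, 1]`. `p = 0` returns the pure ring
#'   lattice; small positive values give the small-world regime.
#' @param require_connected If `TRUE`, regenerate until the realised network
#'   is connected (rewiring can occasionally disconnect it). Off by default:
#'   disconnected realisations are kept and handled naturally by the
#'   diffusion dynamics.
#'
#' @return An [igraph][igraph::igraph-package] graph with graph attributes
#'   `n`, `k` and `p` recording the construction parameters.
#' @examples
#' net <- ws_network(100, 10, 0.01)
#' igraph::ecount(net) # 500
#' @export
ws_network <- function(n, k, p, require_connected = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer")
  }
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2 || k %% 2 != 0) {
    abort("`k` must be an even integer >= 2")
  }
  if (k >= n) {
    abort("`k` must be smaller than `n`")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a probability in [0, 1]")
  }
  for (attempt in seq_len(100L)) {
    g <- igraph::sample_smallworld(
      dim = 1, size = as.integer(n), nei = as.integer(k / 2), p = p,
      loops = FALSE, multiple = FALSE
    )
    if (!require_connected || igraph::is_connected(g)) break
    if (attempt == 100L) {
      abort("failed to generate a connected network in 100 attempts")
    }
  }
  g$n <- as.integer(n)
  g$k <- as.integer(k)
  g$p <- p
  g
}

#' Small deterministic fixture graphs
#'
#' Convenience constructors for the graphs used throughout the test suite and
#' examples: rings, stars, paths and complete graphs.
#'
#' @param type One of `"ring"`, `"star"`, `"path"`, `"complete"`. For
#'   `"star"`, node 1 is the hub.
#' @param n Number of nodes.
#' @return An igraph graph on nodes `1..n`.
#' @export
fixture_graph <- function(type = c("ring", "star", "path", "complete"), n) {
  type <- match.arg(type)
  switch(type,
    ring = igraph::make_ring(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    path = igraph::make_ring(n, circular = FALSE),
    complete = igraph::make_full_graph(n)
  )
}

## sparse adjacency (dgCMatrix) shared by the diffusion kernels; built from
## the raw edge list, which is much cheaper than igraph's converter for the
## tight replication loops
adjacency_of <- function(net) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  Matrix::sparseMatrix(
    i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]),
    x = 1, dims = c(n, n)
  )
}

#' Betweenness centrality scores for every node
#'
#' Unnormalised shortest-path betweenness (Brandes' algorithm). Node pairs
#' joined by several shortest paths contribute fractionally. These scores
#' drive the static centrality-based campaign: high-betweenness nodes sit on
#' bridges between regions of the network, and seeding them with positive
#' influence blocks anti-vaccine communities from merging.
#'
#' @param net An igraph graph (connected or not).
#' @return A tibble with columns `node` and `betweenness` covering every node
#'   exactly once; all scores are non-negative and identically zero on a
#'   complete graph.
#' @examples
#' betweenness_scores(fixture_graph("star", 5)) # hub scores 6, leaves 0
#' @export
betweenness_scores <- function(net) {
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  tibble(node = seq_len(igraph::vcount(net)), betweenness = as.numeric(b))
}

#' Count neighbours of each node by opinion state
#'
#' For each requested node, tallies how many of its neighbours currently hold
#' the negative, neutral and positive opinion. These neighbourhood profiles
#' feed the dynamic local-information campaigns.
#'
#' @param agents Agent table as produced by [init_agents()]: columns `id` and
#'   `opinion` (a vector of the same length as the node set also works).
#' @param net An igraph graph over the same node ids.
#' @param nodes Nodes to report on; defaults to all.
#' @return A tibble with columns `node`, `n_minus`, `n_zero`, `n_plus`;
#'   the three counts always sum to the node degree.
#' @export
neighborhood_counts <- function(agents, net, nodes = NULL) {
  n <- igraph::vcount(net)
  op <- opinion_to_int(if (is.data.frame(agents)) agents$opinion else agents)
  if (length(op) != n) {
    abort("`agents` must hold one opinion per node of `net`")
  }
  nodes <- if (is.null(nodes)) seq_len(n) else as.integer(nodes)
  if (length(nodes) && (anyNA(nodes) || any(nodes < 1L | nodes > n))) {
    abort("unknown node id in `nodes`")
  }
  a <- adjacency_of(net)
  cnt <- neighbor_state_counts(a, op)
  tibble(
    node = nodes,
    n_minus = cnt$n_minus[nodes],
    n_zero = cnt$n_zero[nodes],
    n_plus = cnt$n_plus[nodes]
  )
}

## vectorised neighbour-state tallies for all nodes at once
neighbor_state_counts <- function(a, op) {
  list(
    n_minus = as.integer(a %*% (op == -1L)),
    n_zero = as.integer(a %*% (op == 0L)),
    n_plus = as.integer(a %*% (op == 1L))
  )
}

#' Connected components of an induced subgraph
#'
#' Returns the connected components of the subgraph induced by `subset`,
#' expressed in the original node ids. This is the structural primitive
#' behind the anti-vaccine cluster diagnostics: a positive campaign succeeds
#' partly by carving the would-be anti-vaccine giant component into small,
#' mutually unreachable groups.
#'
#' @param net An igraph graph.
#' @param subset Integer vector of node ids (may be empty).
#' @return A list of integer vectors, one per component, sorted by
#'   decreasing size; their union is exactly `subset` and they are disjoint.
#' @export
subset_components <- function(net, subset) {
  subset <- as.integer(subset)
  if (!length(subset)) {
    return(list())
  }
  n <- igraph::vcount(net)
  if (anyNA(subset) || any(subset < 1L | subset > n)) {
    abort("`subset` contains node ids outside the network")
  }
  subset <- unique(subset)
  sub <- igraph::induced_subgraph(net, subset)
  comp <- igraph::components(sub)
  out <- lapply(unname(split(subset, comp$membership)), sort)
  out[order(-vapply(out, length, 1L))]
}
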
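## Independent oracles used by the tests.  These deliberately avoid the code
## paths (and the igraph algorithms) they are checking.

## adjacency list from an igraph graph, via the raw edge list only
edge_adjlist <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]
    b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## brute-force unnormalised betweenness: BFS distances plus exhaustive
## enumeration of all shortest paths for every node pair
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- edge_adjlist(g)
  bfs_dist <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          q <- c(q, w)
        }
      }
    }
    d
  }
  dist <- t(vapply(seq_len(n), bfs_dist, numeric(n)))
  ## all shortest s->t paths by DFS along strictly-decreasing distance to t
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(v, acc) {
      if (v == t) {
        out[[length(out) + 1L]] <<- acc
        return(invisible())
      }
      for (w in adj[[v]]) {
        if (dist[w, t] == dist[v, t] - 1) walk(w, c(acc, w))
      }
    }
    walk(s, s)
    out
  }
  score <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      ps <- paths_between(s, t)
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        score[inner] <- score[inner] + 1 / length(ps)
      }
    }
  }
  score
}

## union-find partition of `subset` under the edges of g
uf_components <- function(g, subset) {
  if (!length(subset)) {
    return(list())
  }
  parent <- setNames(subset, subset)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  keep <- el[, 1] %in% subset & el[, 2] %in% subset
  for (r in which(keep)) {
    ra <- find(el[r, 1])
    rb <- find(el[r, 2])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(subset, find, numeric(1))
  out <- lapply(unname(split(subset, roots)), sort)
  out[order(-vapply(out, length, 1L))]
}

## global clustering coefficient (transitivity) by dense triangle counting
brute_transitivity <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  triangles <- sum(diag(a %*% a %*% a)) # 6 x number of triangles
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1)) # 2 x number of connected triples
  if (triples == 0) {
    return(NaN)
  }
  triangles / triples
}

## Erdos-Renyi-ish random graph without igraph's samplers
random_small_graph <- function(n, p_edge) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(keep)) g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  g
}

## agents tibble with prescribed opinions, counters frozen at a consistent
## value for committed agents
agents_with_opinions <- function(opinions, theta = 2) {
  n <- length(opinions)
  ag <- init_agents(n)
  ag$opinion <- opinions
  ag$phi_minus <- as.integer(ifelse(opinions == "negative", theta, 0L))
  ag$phi_plus <- as.integer(ifelse(opinions == "positive", theta, 0L))
  ag
}
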
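# Brute-force graph oracles, independent of igraph: plain-R BFS over an
# adjacency matrix, and exhaustive shortest-path enumeration for
# betweenness. Only meant for tiny graphs (n <= ~15).

oracle_bfs_dists <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (is.infinite(d[s, v])) {
            d[s, v] <- lev
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# number of shortest s->v paths, by dynamic programming over BFS levels
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    for (v in order(d[s, ])) {
      if (v == s || is.infinite(d[s, v])) next
      preds <- which(adj[v, ] == 1 & d[s, ] == d[s, v] - 1)
      sig[s, v] <- sum(sig[s, preds])
    }
  }
  sig
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  d <- oracle_bfs_dists(adj)
  sig <- oracle_path_counts(adj, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.finite(d[s, t]) && is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          tot <- tot + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
    b[v] <- tot
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  if (n <= 1) return(rep(0, n))
  d <- oracle_bfs_dists(adj)
  vapply(seq_len(n), function(i) {
    fin <- d[i, -i][is.finite(d[i, -i])]
    if (length(fin) == 0) return(0)
    (length(fin) / (n - 1)) * (length(fin) / sum(fin))
  }, numeric(1))
}

# exact hypergeometric upper tail by enumerating every draw of n from N
oracle_hypergeom <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)   # items 1..K are the successes
  mean(succ >= k)
}

# random simple undirected graph as an adjacency matrix
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adj_to_net <- function(adj, ids = NULL) {
  n <- nrow(adj)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  igraph::V(g)$role <- rep("OTHER_PROTEIN", n)
  g$name <- "test"
  g
}

# small named network from an even-length character vector of endpoints
edge_net <- function(..., isolated = character(0), roles = NULL) {
  ep <- c(...)
  ids <- unique(c(ep, isolated))
  if (is.null(roles)) roles <- setNames(rep("OTHER_PROTEIN", length(ids)), ids)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids, role = roles[ids])
  if (length(ep) > 0) g <- igraph::add_edges(g, ep)
  g$name <- "test"
  g
}
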
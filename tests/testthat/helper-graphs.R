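# Independent oracles and generated fixtures shared across the suite.

# brute-force Floyd-Warshall ASPL, independent of the BFS implementation
brute_aspl <- function(net) {
  n <- igraph::vcount(net)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- edge_matrix(net) + 1L
  for (r in seq_len(nrow(el))) {
    D[el[r, 1L], el[r, 2L]] <- 1
    D[el[r, 2L], el[r, 1L]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  mean(D[upper.tri(D)])
}

# brute-force F2 by explicit enumeration of ordered adjacent pairs
brute_f2 <- function(net, a, b) {
  deg <- degree_sequence(net)
  el <- edge_matrix(net) + 1L
  tot <- 0
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1L]; j <- el[r, 2L]
    tot <- tot + deg[i]^a * deg[j]^b + deg[j]^a * deg[i]^b
  }
  tot
}

# brute-force Newman-Girvan modularity from its definition
brute_modularity <- function(net, assignment) {
  m <- igraph::ecount(net)
  deg <- degree_sequence(net)
  el <- edge_matrix(net) + 1L
  blocks <- unique(assignment)
  q <- 0
  for (bl in blocks) {
    nodes <- which(assignment == bl)
    e_b <- sum(el[, 1L] %in% nodes & el[, 2L] %in% nodes)
    d_b <- sum(deg[nodes])
    q <- q + e_b / m - (d_b / (2 * m))^2
  }
  q
}

# random connected graph: random tree plus random extra edges
random_connected_graph <- function(n, m, seed) {
  fixture_network("er_connected", n, m = m, seed = seed)
}

# random graph that may be disconnected
random_graph <- function(n, m, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2L)) - 1L
  m <- min(m, nrow(pairs))
  network_from_edges(n, pairs[sample.int(nrow(pairs), m), , drop = FALSE])
}

# exact minimum box count for small n: smallest k such that the nodes can be
# partitioned into k boxes of pairwise distance < lb (DFS over assignments)
exact_box_count <- function(net, lb) {
  D <- igraph::distances(net, weights = NA)
  n <- nrow(D)
  compatible <- D < lb
  assign_ok <- function(v, boxes, k) {
    if (v > n) return(TRUE)
    for (b in seq_len(min(k, length(boxes) + 1L))) {
      mem <- if (b <= length(boxes)) boxes[[b]] else integer(0)
      if (all(compatible[v, mem])) {
        nb <- boxes
        nb[[b]] <- c(mem, v)
        if (assign_ok(v + 1L, nb, k)) return(TRUE)
      }
    }
    FALSE
  }
  for (k in 1:n) {
    if (assign_ok(1L, list(), k)) return(k)
  }
  n
}
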
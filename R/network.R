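# Undirected simple-graph representation and exact structural measures.
# Networks are igraph objects; the constructors below are the only sanctioned
# way to build them from raw edges, and they enforce simplicity (no self-loops,
# no parallel edges) and dense 0-based node ids.

#' Build a simple undirected network from a 0-based edge matrix
#'
#' @param n_nodes number of nodes; node ids are `0..n_nodes-1`.
#' @param edges two-column matrix (or data frame) of 0-based endpoint ids, one
#'   row per undirected edge. `NULL` or zero rows gives an edgeless graph.
#' @return an undirected [igraph][igraph::igraph-package] graph with
#'   `n_nodes` vertices.
#' @examples
#' net <- network_from_edges(4, rbind(c(0, 1), c(0, 2), c(0, 3)))  # star
#' degree_sequence(net)
#' @export
network_from_edges <- function(n_nodes, edges = NULL) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 1)
  n <- as.integer(n_nodes)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    return(g)
  }
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  if (anyNA(edges)) stop("edge endpoints must be integers")
  if (any(edges < 0L) || any(edges >= n)) {
    stop("node ids must lie in 0..n_nodes-1")
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  key <- pmin(edges[, 1L], edges[, 2L]) * n + pmax(edges[, 1L], edges[, 2L])
  if (anyDuplicated(key) > 0L) stop("duplicate edges are not allowed")
  igraph::add_edges(g, t(edges + 1L))
}

#' Extract the canonical 0-based edge matrix of a network
#'
#' Rows are `(min, max)` pairs sorted lexicographically, so equal networks
#' always produce identical matrices.
#'
#' @param net an igraph network.
#' @return integer matrix with columns `from`, `to`.
#' @export
edge_matrix <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  }
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])) - 1L
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  storage.mode(el) <- "integer"
  dimnames(el) <- list(NULL, c("from", "to"))
  el
}

#' Degree sequence
#'
#' @param net an igraph network.
#' @return integer vector of node degrees, in node-id order.
#' @export
degree_sequence <- function(net) {
  as.integer(igraph::degree(net))
}

#' Is the network connected?
#'
#' @param net an igraph network with at least one node.
#' @return `TRUE` iff every node is reachable from node 0.
#' @export
is_connected_network <- function(net) {
  stopifnot(igraph::vcount(net) >= 1L)
  igraph::is_connected(net)
}

#' Average shortest path length (hops)
#'
#' Mean BFS hop distance over all unordered distinct node pairs. For a
#' connected network on \eqn{n} nodes the value lies in
#' \eqn{[1, (n+1)/3]} — the complete graph and the path attain the bounds.
#'
#' @param net a connected igraph network with at least 2 nodes.
#' @return mean pairwise hop distance.
#' @export
avg_shortest_path <- function(net) {
  if (igraph::vcount(net) < 2L) stop("average shortest path needs at least 2 nodes")
  if (!igraph::is_connected(net)) {
    stop("network is disconnected: average shortest path length is undefined")
  }
  igraph::mean_distance(net, directed = FALSE, unconnected = FALSE)
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local transitivity (triangles through the node over
#' `k(k-1)/2`); nodes with degree < 2 contribute 0.
#'
#' @param net an igraph network with at least 3 nodes.
#' @return ratio in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(igraph::vcount(net) >= 3L)
  loc <- igraph::transitivity(net, type = "local")
  loc[is.na(loc)] <- 0
  mean(loc)
}

#' Network diameter (hops)
#'
#' @param net a connected igraph network.
#' @return maximum pairwise BFS distance.
#' @export
net_diameter <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("network is disconnected: diameter is undefined")
  }
  as.integer(igraph::diameter(net, weights = NA))
}
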
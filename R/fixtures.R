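# Deterministic fixture networks with known closed-form structure:
# ASPL(path P_n) = (n+1)/3, ASPL(star S_n) = 2(n-1)/n, ASPL(K_n) = 1.

#' Fixture networks
#'
#' @param kind one of `"path"`, `"cycle"`, `"star"`, `"complete"`,
#'   `"ring_lattice"`, `"er_connected"`.
#' @param n node count.
#' @param m edge count, for `"er_connected"` (random spanning tree plus
#'   uniformly random extra edges, so connectivity is guaranteed).
#' @param k neighbours on each side, for `"ring_lattice"`.
#' @param seed RNG seed, for `"er_connected"`.
#' @return an igraph network.
#' @examples
#' avg_shortest_path(fixture_network("path", 4))  # 5/3
#' @export
fixture_network <- function(kind = c("path", "cycle", "star", "complete",
                                     "ring_lattice", "er_connected"),
                            n, m = NULL, k = 1, seed = 1) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  switch(kind,
    path = {
      stopifnot(n >= 2L)
      network_from_edges(n, cbind(0:(n - 2L), 1:(n - 1L)))
    },
    cycle = {
      stopifnot(n >= 3L)
      network_from_edges(n, cbind(0:(n - 1L), c(1:(n - 1L), 0L)))
    },
    star = {
      stopifnot(n >= 2L)
      network_from_edges(n, cbind(0L, 1:(n - 1L)))
    },
    complete = {
      stopifnot(n >= 2L)
      network_from_edges(n, t(combn(n, 2L)) - 1L)
    },
    ring_lattice = {
      stopifnot(n >= 3L, k >= 1, 2L * k < n)
      g <- igraph::make_lattice(length = n, dim = 1, nei = k, circular = TRUE)
      network_from_edges(n, edge_matrix(g))
    },
    er_connected = {
      stopifnot(!is.null(m), m >= n - 1L)
      p <- model_params(n = n, m = m, a = 0, b = 0, xmin = 1,
                        c = min((n + 1) / 3, 2))
      initial_network(p, seed = seed)
    })
}
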
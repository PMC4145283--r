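# The model's two objectives and constraint evaluation.
#
# F1 = sum of node degrees (minimised); F2 = sum over ORDERED adjacent pairs
# (i, j) of x_i^a * x_j^b (maximised). The ordered-pair convention is
# normative: it is the only one under which F2 reduces exactly to F1 when
# a = b = 0 (each undirected edge contributes both orientations, i.e.
# x_i^0 x_j^0 + x_j^0 x_i^0 = 2, and F1 = 2m).

#' Model parameters
#'
#' @param n node count (>= 2).
#' @param m edge budget; fixing `m` fixes `F1 = 2m` (the "histogram method").
#' @param a,b non-negative exponents of the generalised edge degree
#'   \eqn{x_i^a x_j^b}. `(0,0)` gives constant edge degree 1, `(0,1)` the
#'   neighbour degree, `(1,1)` the degree product.
#' @param xmin minimum node degree enforced network-wide (>= 1).
#' @param c target average shortest path length, in `[1, (n+1)/3]`.
#' @return an object of class `model_params`.
#' @examples
#' model_params(n = 300, m = 762, a = 0, b = 1, xmin = 2, c = 3.9)
#' @export
model_params <- function(n, m, a = 0, b = 1, xmin = 1, c) {
  n <- as.integer(n); m <- as.integer(m); xmin <- as.integer(xmin)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  bad <- function(msg) {
    stop(structure(
      class = c("paretonet_infeasible", "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  if (is.na(n) || n < 2L) bad("n must be an integer >= 2")
  if (is.na(m) || m < n - 1L) bad(sprintf("m = %d cannot connect n = %d nodes (need m >= n-1)", m, n))
  if (m > n * (n - 1L) / 2L) bad("m exceeds the number of node pairs")
  if (is.na(a) || is.na(b) || a < 0 || b < 0) bad("exponents a, b must be non-negative")
  if (is.na(xmin) || xmin < 1L) bad("xmin must be a count >= 1")
  if (xmin * n > 2L * m) bad(sprintf("degree floor infeasible: xmin*n = %d > 2m = %d", xmin * n, 2L * m))
  if (is.na(c) || c < 1 || c > (n + 1) / 3) {
    bad(sprintf("c must lie in [1, (n+1)/3] = [1, %.4g]", (n + 1) / 3))
  }
  structure(list(n = n, m = m, a = a, b = b, xmin = xmin, c = c),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Model parameters: n = %d, m = %d (F1 = %d), a = %g, b = %g, xmin = %d, c = %g\n",
    x$n, x$m, 2L * x$m, x$a, x$b, x$xmin, x$c))
  invisible(x)
}

#' Generalised edge degree of a single edge
#'
#' \eqn{x_i^a x_j^b}: the product of power functions of the end-node degrees.
#' Special cases: constant 1 (`a = b = 0`), neighbour degree (`a = 0, b = 1`),
#' degree product (`a = b = 1`).
#'
#' @param xi,xj degrees of the two end nodes (>= 1); vectorised.
#' @param a,b non-negative exponents.
#' @return non-negative numeric.
#' @export
edge_degree <- function(xi, xj, a, b) {
  if (any(xi < 1) || any(xj < 1)) {
    stop("degenerate node: edge-degree endpoints must have degree >= 1")
  }
  if (a < 0 || b < 0) stop("exponents a, b must be non-negative")
  xi^a * xj^b
}

#' Total node degree F1
#'
#' @param net an igraph network.
#' @return `sum(degree) = 2 * |edges|`.
#' @export
f1 <- function(net) {
  sum(degree_sequence(net))
}

#' Total generalised edge degree F2
#'
#' Sum over ordered adjacent pairs `(i, j)` of `degree(i)^a * degree(j)^b`;
#' each undirected edge contributes both orientations, so `f2` with
#' `a = b = 0` equals [f1()] exactly. With a [similarity_model()], each term
#' is divided by the pair's similarity distance (1 within a block, `delta`
#' across blocks), which penalises cross-community hub linking.
#'
#' @param net an igraph network.
#' @param a,b non-negative exponents.
#' @param sim optional [similarity_model()]; `NULL` for the plain objective.
#' @return non-negative numeric.
#' @export
f2 <- function(net, a, b, sim = NULL) {
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0L) return(0)
  deg <- degree_sequence(net)
  du <- deg[el[, 1L]]
  dv <- deg[el[, 2L]]
  terms <- du^a * dv^b + dv^a * du^b
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "similarity_model"))
    blk <- sim$assignment
    if (length(blk) != igraph::vcount(net)) {
      stop("similarity model assignment length does not match node count")
    }
    w <- ifelse(blk[el[, 1L]] == blk[el[, 2L]], 1, 1 / sim$delta)
    terms <- terms * w
  }
  sum(terms)
}

#' Evaluate a network against the model
#'
#' Populates both objectives, the achieved average shortest path length and
#' the feasibility verdict: connected, minimum degree >= `xmin`, edge count
#' equal to `m`, and `|y - c| <= tol`.
#'
#' @param net an igraph network.
#' @param params a [model_params()] object.
#' @param tol constraint tolerance in hops (default 0.05).
#' @return an object of class `objective_value` with fields `f1`, `f2`, `y`
#'   (`NA` if disconnected), `constraint_gap`, `feasible`, and the individual
#'   feasibility flags.
#' @export
evaluate_objective <- function(net, params, tol = 0.05) {
  stopifnot(inherits(params, "model_params"))
  deg <- degree_sequence(net)
  connected <- is_connected_network(net)
  y <- if (connected && igraph::vcount(net) >= 2L) avg_shortest_path(net) else NA_real_
  gap <- if (is.na(y)) NA_real_ else abs(y - params$c)
  edge_count_ok <- igraph::ecount(net) == params$m
  floor_ok <- min(deg) >= params$xmin
  gap_ok <- !is.na(gap) && gap <= tol
  structure(list(
    f1 = sum(deg),
    f2 = f2(net, params$a, params$b),
    y = y,
    constraint_gap = gap,
    feasible = connected && floor_ok && edge_count_ok && gap_ok,
    connected = connected,
    min_degree_ok = floor_ok,
    edge_count_ok = edge_count_ok,
    tol = tol
  ), class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf(
    "F1 = %g, F2 = %g, y = %s, |y - c| = %s, feasible = %s\n",
    x$f1, x$f2,
    if (is.na(x$y)) "NA (disconnected)" else sprintf("%.4f", x$y),
    if (is.na(x$constraint_gap)) "NA" else sprintf("%.4f", x$constraint_gap),
    x$feasible))
  invisible(x)
}
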
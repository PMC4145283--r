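# File formats and run reports. The canonical on-disk form is a two-column
# 0-based edge-list TSV; GraphML is available for attribute-bearing export.

#' Read a network from an edge-list TSV
#'
#' Two integer columns (0-based node ids), `#` comments allowed. Nodes are
#' inferred as `0..max(id)`. Self-loops, duplicate edges and malformed lines
#' are errors reported with their line number.
#'
#' @param path file path.
#' @return an igraph network.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  if (length(keep) == 0L) stop(sprintf("empty edge list: %s", path))
  edges <- matrix(NA_integer_, length(keep), 2L)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    tok <- strsplit(stripped[ln], "[ \t]+")[[1]]
    vals <- suppressWarnings(as.integer(tok))
    if (length(tok) != 2L || anyNA(vals) || any(vals < 0L)) {
      stop(sprintf("line %d: expected two non-negative integer node ids, got '%s'",
                   ln, lines[ln]))
    }
    if (vals[1L] == vals[2L]) {
      stop(sprintf("line %d: self-loop %d-%d is not allowed", ln, vals[1L], vals[2L]))
    }
    edges[i, ] <- vals
  }
  n <- max(edges) + 1L
  key <- pmin(edges[, 1L], edges[, 2L]) * n + pmax(edges[, 1L], edges[, 2L])
  dup <- anyDuplicated(key)
  if (dup > 0L) {
    stop(sprintf("line %d: duplicate edge %d-%d", keep[dup], edges[dup, 1L], edges[dup, 2L]))
  }
  network_from_edges(n, edges)
}

#' Write a network as an edge-list TSV
#'
#' Edges are written as `(min, max)` pairs in lexicographic order, so equal
#' networks always produce byte-identical files.
#'
#' @param net an igraph network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- edge_matrix(net)
  writeLines(sprintf("%d\t%d", el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Standard GraphML with the node degree attached as a vertex attribute.
#'
#' @param net an igraph network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::V(net)$degree <- degree_sequence(net)
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a degree histogram as a two-column TSV
#'
#' @param net an igraph network (or an integer degree vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_degree_histogram <- function(net, path) {
  deg <- if (is.numeric(net)) as.integer(net) else degree_sequence(net)
  tab <- table(deg)
  writeLines(c("degree\tcount",
               sprintf("%s\t%d", names(tab), as.integer(tab))), path)
  invisible(path)
}

#' Read / write a node-to-block assignment TSV
#'
#' Two columns: `node_id` (0-based, must cover `0..n-1`) and `block_label`.
#'
#' @param path file path.
#' @return integer block labels in node-id order.
#' @export
read_block_assignment <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("node_id", "block_label"))
  n <- nrow(df)
  if (!setequal(df$node_id, 0:(n - 1L))) {
    stop("block assignment must cover node ids 0..n-1 exactly once")
  }
  df$block_label[order(df$node_id)]
}

#' @rdname read_block_assignment
#' @param assignment block labels, length `n`.
#' @export
write_block_assignment <- function(assignment, path) {
  writeLines(sprintf("%d\t%s", seq_along(assignment) - 1L, assignment), path)
  invisible(path)
}

#' Machine-readable run report
#'
#' Everything needed to reproduce the run — resolved parameters,
#' configuration, seed — plus the achieved objectives. `F2` is reported in
#' both pair conventions (ordered-pair, the normative one, and its half, the
#' unordered sum). Timing is deliberately excluded so reports are diffable.
#'
#' @param result a `run_result` from [optimise_network()].
#' @param fit optional `fit_result` to embed.
#' @param fractal optional `box_covering_result` to embed.
#' @return a list ready for JSON serialisation.
#' @export
run_report <- function(result, fit = NULL, fractal = NULL) {
  stopifnot(inherits(result, "run_result"))
  p <- result$params
  cfg <- result$config
  rep <- list(
    schema = "1",
    params = list(n = p$n, m = p$m, a = p$a, b = p$b, xmin = p$xmin, c = p$c),
    config = list(tol = cfg$tol,
                  max_iters = if (is.null(cfg$max_iters)) 3000 * p$m else cfg$max_iters,
                  patience = if (is.null(cfg$patience)) 20 * p$m else cfg$patience,
                  retry_limit = cfg$retry_limit, restarts = cfg$restarts,
                  aspl_sample_k = cfg$aspl_sample_k),
    seed = result$seed,
    success = result$success,
    accepted_moves = result$accepted_moves,
    f1 = result$objective$f1,
    f2_ordered = result$f2_ordered,
    f2_unordered = result$f2_unordered,
    y = result$objective$y,
    constraint_gap = result$objective$constraint_gap,
    feasible = result$objective$feasible
  )
  if (!is.null(result$sim)) {
    rep$community <- list(k = result$sim$k, delta = result$sim$delta)
  }
  if (!is.null(fit)) {
    rep$fit <- list(gamma_hat = fit$gamma_hat, xmin_used = fit$xmin_used,
                    ks = fit$ks, n_tail = fit$n_tail)
  }
  if (!is.null(fractal)) {
    rep$box_covering <- list(lb = fractal$lb_values, nb = fractal$nb_values,
                             db = fractal$db, r2 = fractal$r2)
  }
  rep
}

#' Serialise a report to JSON
#'
#' @param report a list from [run_report()].
#' @param path optional output path; `NULL` returns the JSON string.
#' @return JSON string, invisibly if written to `path`.
#' @export
write_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
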
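#' Node degrees of a signed graph
#'
#' Degree counts incident edges on the unsigned skeleton; weight and sign
#' are ignored.
#'
#' @param graph A `signed_graph`.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
node_degrees <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  d <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0) {
    t1 <- table(graph$edges$from)
    t2 <- table(graph$edges$to)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Hubs: the most-connected nodes
#'
#' Nodes ranked by degree (descending), ties broken lexicographically by
#' name. The list is cut after `top_k` entries but keeps every node tied
#' with the k-th degree, so a hub never drops out by an arbitrary tie split.
#' The default `top_k = 3` reflects how many hubs a stratum network of this
#' size typically exposes.
#'
#' @param graph A `signed_graph`.
#' @param top_k Positive integer.
#' @return Data frame with columns `node`, `degree`.
#' @export
hubs <- function(graph, top_k = 3) {
  stopifnot(top_k >= 1)
  d <- node_degrees(graph)
  ord <- order(-d, names(d))
  d <- d[ord]
  k <- min(top_k, length(d))
  keep <- d >= d[[k]]
  data.frame(node = names(d)[keep], degree = as.integer(d[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bridge nodes (articulation points)
#'
#' A bridge node is one whose removal splits its connected component —
#' formally an articulation point: removal strictly increases the number of
#' connected components among the remaining nodes. Bridge nodes mark the
#' couplings between otherwise separate subsystems of correlated features.
#'
#' @param graph A `signed_graph`.
#' @return Sorted character vector of node names (possibly empty).
#' @export
bridge_nodes <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  if (nrow(graph$edges) == 0) return(character(0))
  g <- as_igraph(graph)
  sort(igraph::V(g)$name[igraph::articulation_points(g)])
}

#' Connected components
#'
#' @param graph A `signed_graph`.
#' @return List of character vectors (each sorted), ordered by decreasing
#'   size then by lexicographic minimum element.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  sets <- split(igraph::V(g)$name, comp$membership)
  sets <- lapply(sets, sort)
  mins <- vapply(sets, `[`, character(1), 1)
  sizes <- lengths(sets)
  sets <- sets[order(-sizes, mins)]
  names(sets) <- NULL
  sets
}

#' Descriptive topology summary
#'
#' Bundles degrees, hubs, bridge nodes and connected components of a graph.
#'
#' @param graph A `signed_graph`.
#' @param top_k Hub list size passed to [hubs()].
#' @return Object of class `topology_summary`.
#' @export
topology_summary <- function(graph, top_k = 3) {
  structure(list(
    degrees = node_degrees(graph),
    hubs = hubs(graph, top_k = top_k),
    bridges = bridge_nodes(graph),
    components = connected_components(graph),
    n_edges = n_edges(graph)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("topology:", length(x$degrees), "nodes,", x$n_edges, "edges,",
      length(x$components), "components\n")
  cat("hubs:", paste(sprintf("%s(%d)", x$hubs$node, x$hubs$degree), collapse = ", "), "\n")
  cat("bridges:", if (length(x$bridges)) paste(x$bridges, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# JSON-friendly representation used by the pipeline report.
topology_as_list <- function(ts) {
  list(
    degrees = as.list(ts$degrees),
    hubs = lapply(seq_len(nrow(ts$hubs)), function(i) {
      list(node = ts$hubs$node[i], degree = ts$hubs$degree[i])
    }),
    bridges = as.list(ts$bridges),
    components = lapply(ts$components, as.list),
    n_edges = ts$n_edges
  )
}
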
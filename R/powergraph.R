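#' Maximal cliques of a signed graph
#'
#' Enumerates all maximal cliques of the unsigned skeleton with at least
#' `min_size` members. Cliques are the motif of interest here: a set of
#' features in which every pair is correlated above the cutoff behaves as a
#' single subsystem. The default `min_size = 3` matches the 3-5 node motif
#' range typical of these networks.
#'
#' @param graph A `signed_graph`.
#' @param min_size Minimum clique size (>= 2).
#' @return List of sorted character vectors, ordered by decreasing size then
#'   lexicographically.
#' @export
maximal_cliques <- function(graph, min_size = 3) {
  stopifnot(inherits(graph, "signed_graph"), min_size >= 2)
  if (nrow(graph$edges) == 0) return(list())
  g <- as_igraph(graph)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(-lengths(cl), keys)]
}

# unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Candidate power-node sets: all subtrees of a complete-linkage dendrogram
# over Jaccard distance of closed neighborhoods, plus all maximal cliques
# (size >= 2), plus singletons. Candidates only propose; the greedy cover
# verifies every expanded pair against real uncovered edges.
.candidate_sets <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  cand <- as.list(nodes)
  if (n >= 2 && nrow(graph$edges) > 0) {
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    adj[cbind(graph$edges$from, graph$edges$to)] <- TRUE
    adj <- adj | t(adj)
    closed <- adj
    diag(closed) <- TRUE
    inter <- tcrossprod(closed * 1)
    sizes <- diag(inter)
    uni <- outer(sizes, sizes, `+`) - inter
    jac <- inter / pmax(uni, 1)
    hc <- stats::hclust(stats::as.dist(1 - jac), method = "complete")
    sets <- vector("list", n - 1)
    for (i in seq_len(n - 1)) {
      members <- character(0)
      for (j in hc$merge[i, ]) {
        members <- c(members,
                     if (j < 0) hc$labels[-j] else sets[[j]])
      }
      sets[[i]] <- members
    }
    cand <- c(cand, lapply(sets, sort))
    cand <- c(cand, maximal_cliques(graph, min_size = 2))
  }
  keys <- vapply(cand, paste, character(1), collapse = "\r")
  cand[!duplicated(keys)]
}

# TRUE if two sets can coexist as power nodes: equal, disjoint, or nested.
.sets_compatible <- function(a, b) {
  k <- length(intersect(a, b))
  k == 0 || k == length(a) || k == length(b)
}

#' Power-graph decomposition of a signed graph
#'
#' Losslessly compresses a graph into *power nodes* (feature sets) and
#' *power edges*: a clique self-edge on a set expands to all within-set
#' pairs, a biclique edge between two disjoint sets expands to all cross
#' pairs. Every source edge is covered exactly once, by one power edge or as
#' one residual edge, so expanding the decomposition reproduces the source
#' graph edge-for-edge.
#'
#' The construction is a deterministic greedy exact edge cover: candidate
#' sets come from complete-linkage clustering of nodes under Jaccard
#' similarity of closed neighborhoods (every dendrogram subtree) plus all
#' maximal cliques; at each step the feasible candidate power edge covering
#' the most uncovered edges is selected (ties: fewer total members, then
#' lexicographic), subject to every expanded pair being a real uncovered
#' edge and to power-node sets remaining disjoint or nested; the loop stops
#' when no candidate covers at least 2 uncovered edges.
#'
#' Modules are detected on the unsigned skeleton; the sign mix of each
#' module is reported by [module_report()].
#'
#' @param graph A `signed_graph`.
#' @param min_module Minimum members per power node (and per biclique side),
#'   default 2.
#' @return Object of class `power_graph`: `power_nodes` (named list of
#'   member sets), `power_edges` (data frame `a`, `b`, `kind`; `a == b` for
#'   clique self-edges), `residual_edges`, and the source graph.
#' @export
power_decompose <- function(graph, min_module = 2) {
  stopifnot(inherits(graph, "signed_graph"), min_module >= 1)
  nodes <- graph$nodes
  n <- length(nodes)
  empty_pg <- function(residual) {
    structure(list(
      nodes = nodes,
      power_nodes = stats::setNames(list(), character(0)),
      power_edges = data.frame(a = character(0), b = character(0),
                               kind = character(0), stringsAsFactors = FALSE),
      residual_edges = residual,
      source = graph,
      min_module = min_module
    ), class = "power_graph")
  }
  if (nrow(graph$edges) == 0) return(empty_pg(graph$edges))

  unc <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  unc[cbind(graph$edges$from, graph$edges$to)] <- TRUE
  unc <- unc | t(unc)

  cand <- .candidate_sets(graph)
  cand <- cand[lengths(cand) >= min_module]
  sizes <- lengths(cand)
  keys <- vapply(cand, paste, character(1), collapse = "\r")
  ord <- order(keys)
  cand <- cand[ord]; sizes <- sizes[ord]; keys <- keys[ord]
  nc <- length(cand)

  selected_sets <- list()     # power node member sets, in id order
  selected_keys <- character(0)
  pe_a <- pe_b <- pe_kind <- character(0)

  get_pn_id <- function(set) {
    key <- paste(set, collapse = "\r")
    hit <- match(key, selected_keys)
    if (!is.na(hit)) return(names(selected_sets)[hit])
    id <- sprintf("P%d", length(selected_sets) + 1L)
    selected_sets[[id]] <<- set
    selected_keys <<- c(selected_keys, key)
    id
  }

  repeat {
    best_cov <- 1L
    best <- NULL

    compatible <- function(set) {
      for (s in selected_sets) if (!.sets_compatible(set, s)) return(FALSE)
      TRUE
    }
    comp_ok <- vapply(cand, compatible, logical(1))

    # clique self-edges
    for (ci in which(comp_ok & sizes >= max(2, min_module))) {
      s <- cand[[ci]]
      sub <- unc[s, s]
      cov <- sum(sub[upper.tri(sub)])
      npairs <- length(s) * (length(s) - 1) / 2
      if (cov == npairs && cov >= 2) {
        rec <- list(cov = cov, total = length(s), id = keys[ci],
                    kind = "clique", a = s, b = s)
        if (is.null(best) || cov > best_cov ||
            (cov == best_cov && (rec$total < best$total ||
             (rec$total == best$total && rec$id < best$id)))) {
          best <- rec; best_cov <- cov
        }
      }
    }
    # biclique edges between disjoint compatible candidate pairs
    ok_idx <- which(comp_ok & sizes >= min_module)
    for (ii in seq_along(ok_idx)) {
      i <- ok_idx[ii]
      s <- cand[[i]]
      for (jj in seq_len(ii - 1L)) {
        j <- ok_idx[jj]
        t_ <- cand[[j]]
        if (length(intersect(s, t_)) > 0) next
        cov <- sum(unc[s, t_])
        if (cov != length(s) * length(t_) || cov < 2) next
        if (cov < best_cov) next
        id <- paste(sort(c(keys[i], keys[j])), collapse = "\n")
        rec <- list(cov = cov, total = length(s) + length(t_), id = id,
                    kind = "biclique",
                    a = if (keys[i] < keys[j]) s else t_,
                    b = if (keys[i] < keys[j]) t_ else s)
        if (is.null(best) || cov > best_cov ||
            (cov == best_cov && (rec$total < best$total ||
             (rec$total == best$total && rec$id < best$id)))) {
          best <- rec; best_cov <- cov
        }
      }
    }

    if (is.null(best) || best_cov < 2) break
    if (best$kind == "clique") {
      unc[best$a, best$a] <- FALSE
      ida <- get_pn_id(best$a)
      pe_a <- c(pe_a, ida); pe_b <- c(pe_b, ida); pe_kind <- c(pe_kind, "clique")
    } else {
      unc[best$a, best$b] <- FALSE
      unc[best$b, best$a] <- FALSE
      ida <- get_pn_id(best$a)
      idb <- get_pn_id(best$b)
      pe_a <- c(pe_a, ida); pe_b <- c(pe_b, idb); pe_kind <- c(pe_kind, "biclique")
    }
  }

  resid_keep <- unc[cbind(graph$edges$from, graph$edges$to)]
  residual <- graph$edges[resid_keep, , drop = FALSE]
  rownames(residual) <- NULL
  pg <- empty_pg(residual)
  pg$power_nodes <- selected_sets
  pg$power_edges <- data.frame(a = pe_a, b = pe_b, kind = pe_kind,
                               stringsAsFactors = FALSE)
  pg
}

#' @export
print.power_graph <- function(x, ...) {
  cat("power_graph:", length(x$power_nodes), "power nodes,",
      nrow(x$power_edges), "power edges,",
      nrow(x$residual_edges), "residual edges\n")
  invisible(x)
}

#' Expand a power graph back to a plain edge set
#'
#' Expands every power edge (all within-set pairs for a clique self-edge,
#' all cross pairs for a biclique) and appends the residual edges. For any
#' decomposition produced by [power_decompose()] this reproduces the source
#' graph's edge set exactly.
#'
#' @param pg A `power_graph`.
#' @return Data frame with columns `from`, `to` (each row `from < to`),
#'   sorted.
#' @export
expand_power_graph <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  from <- character(0); to <- character(0)
  for (i in seq_len(nrow(pg$power_edges))) {
    a <- pg$power_nodes[[pg$power_edges$a[i]]]
    b <- pg$power_nodes[[pg$power_edges$b[i]]]
    if (pg$power_edges$kind[i] == "clique") {
      prs <- utils::combn(sort(a), 2)
      from <- c(from, prs[1, ]); to <- c(to, prs[2, ])
    } else {
      g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      from <- c(from, pmin(g$a, g$b)); to <- c(to, pmax(g$a, g$b))
    }
  }
  from <- c(from, pg$residual_edges$from)
  to <- c(to, pg$residual_edges$to)
  out <- data.frame(from = pmin(from, to), to = pmax(from, to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the modules of a power graph
#'
#' Per power edge: members, kind, number of covered source edges, mean
#' absolute correlation, count of positive and negative edges, and (when
#' `labels` supplies feature categories such as structural/adaptive) the
#' category composition. Also reports the compression ratio, source edges
#' over (power edges + residual edges); `NA` for an empty graph.
#'
#' @param pg A `power_graph`.
#' @param labels Optional named character vector, feature -> category.
#'   Unknown feature names raise a warning, not an error.
#' @return Object of class `module_report`: list with `modules` (data
#'   frame) and compression statistics.
#' @export
module_report <- function(pg, labels = NULL) {
  stopifnot(inherits(pg, "power_graph"))
  if (!is.null(labels)) {
    bad <- setdiff(names(labels), pg$nodes)
    if (length(bad) > 0) {
      warning("labels name unknown feature(s): ", paste(bad, collapse = ", "))
    }
  }
  src <- pg$source$edges
  rmap <- stats::setNames(src$r, .pair_key(src$from, src$to))
  npe <- nrow(pg$power_edges)
  rows <- vector("list", npe)
  for (i in seq_len(npe)) {
    a <- pg$power_nodes[[pg$power_edges$a[i]]]
    b <- pg$power_nodes[[pg$power_edges$b[i]]]
    kind <- pg$power_edges$kind[i]
    if (kind == "clique") {
      prs <- utils::combn(sort(a), 2)
      kk <- .pair_key(prs[1, ], prs[2, ])
    } else {
      g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      kk <- .pair_key(g$a, g$b)
    }
    rs <- rmap[kk]
    members <- sort(union(a, b))
    cats <- ""
    if (!is.null(labels)) {
      lab <- unname(labels[members])
      lab[is.na(lab)] <- "unlabelled"
      tt <- table(lab)
      cats <- paste(sprintf("%s:%d", names(tt), as.integer(tt)), collapse = ",")
    }
    rows[[i]] <- data.frame(
      module = sprintf("M%d", i),
      kind = kind,
      members = paste(members, collapse = ","),
      n_members = length(members),
      covered_edges = length(rs),
      mean_abs_r = mean(abs(rs)),
      n_positive = sum(rs > 0),
      n_negative = sum(rs < 0),
      categories = cats,
      stringsAsFactors = FALSE
    )
  }
  modules <- if (npe > 0) do.call(rbind, rows) else data.frame(
    module = character(0), kind = character(0), members = character(0),
    n_members = integer(0), covered_edges = integer(0),
    mean_abs_r = numeric(0), n_positive = integer(0),
    n_negative = integer(0), categories = character(0),
    stringsAsFactors = FALSE
  )
  n_src <- nrow(src)
  n_res <- nrow(pg$residual_edges)
  ratio <- if (n_src == 0) NA_real_ else n_src / (npe + n_res)
  structure(list(
    modules = modules,
    n_source_edges = n_src,
    n_power_edges = npe,
    n_residual_edges = n_res,
    compression_ratio = ratio
  ), class = "module_report")
}

#' @export
print.module_report <- function(x, ...) {
  cat("module report:", x$n_power_edges, "modules,",
      x$n_residual_edges, "residual edges, compression ratio",
      if (is.na(x$compression_ratio)) "NA" else
        format(x$compression_ratio, digits = 4), "\n")
  if (nrow(x$modules) > 0) print(x$modules, row.names = FALSE)
  invisible(x)
}

# JSON-friendly representation used by the pipeline report.
module_report_as_list <- function(mr) {
  list(
    modules = lapply(seq_len(nrow(mr$modules)), function(i) as.list(mr$modules[i, ])),
    n_source_edges = mr$n_source_edges,
    n_power_edges = mr$n_power_edges,
    n_residual_edges = mr$n_residual_edges,
    compression_ratio = if (is.na(mr$compression_ratio)) NULL else mr$compression_ratio
  )
}

#' Write a power graph as GraphML
#'
#' Plain-node GraphML carrying each node's `power_node_id` (innermost
#' containing power node, empty if none) and each source edge's covering
#' power edge `kind` (`clique`, `biclique` or `residual`).
#'
#' @param pg A `power_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_graphml <- function(pg, path) {
  stopifnot(inherits(pg, "power_graph"))
  pn_of <- stats::setNames(rep("", length(pg$nodes)), pg$nodes)
  for (id in names(pg$power_nodes)) {
    mem <- pg$power_nodes[[id]]
    # innermost = smallest containing set wins
    for (v in mem) {
      cur <- pn_of[[v]]
      if (cur == "" || length(pg$power_nodes[[cur]]) > length(mem)) pn_of[v] <- id
    }
  }
  kind_of <- stats::setNames(rep("residual", nrow(pg$source$edges)),
                             .pair_key(pg$source$edges$from, pg$source$edges$to))
  for (i in seq_len(nrow(pg$power_edges))) {
    a <- pg$power_nodes[[pg$power_edges$a[i]]]
    b <- pg$power_nodes[[pg$power_edges$b[i]]]
    if (pg$power_edges$kind[i] == "clique") {
      prs <- utils::combn(sort(a), 2)
      kk <- .pair_key(prs[1, ], prs[2, ])
    } else {
      g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      kk <- .pair_key(g$a, g$b)
    }
    kind_of[kk] <- pg$power_edges$kind[i]
  }
  ids <- stats::setNames(sprintf("n%d", seq_along(pg$nodes) - 1L), pg$nodes)
  e <- pg$source$edges
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="v_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="v_pn" for="node" attr.name="power_node_id" attr.type="string"/>',
    '  <key id="e_kind" for="edge" attr.name="kind" attr.type="string"/>',
    '  <key id="e_r" for="edge" attr.name="r" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"><data key="v_name">%s</data><data key="v_pn">%s</data></node>',
            ids, pg$nodes, pn_of[pg$nodes]),
    if (nrow(e) > 0) {
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="e_kind">%s</data>',
                     '<data key="e_r">%.17g</data></edge>'),
              ids[e$from], ids[e$to], kind_of[.pair_key(e$from, e$to)], e$r)
    },
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path)
  invisible(path)
}
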
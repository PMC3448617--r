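#' Sample Pearson correlation of two vectors
#'
#' Direct evaluation of r = cov(x, y) / (s_x s_y) with matching denominators
#' in numerator and denominator, so the result does not depend on the n vs
#' n - 1 convention.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param x_name,y_name Optional names used in degenerate-feature error
#'   messages.
#' @return Scalar in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(1:5, c(2, 1, 4, 3, 6))
pearson_r <- function(x, y, x_name = "x", y_name = "y") {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  cx <- x - mean(x)
  cy <- y - mean(y)
  sxx <- sum(cx^2)
  syy <- sum(cy^2)
  if (sxx == 0) stop("degenerate feature '", x_name, "': zero variance")
  if (syy == 0) stop("degenerate feature '", y_name, "': zero variance")
  r <- sum(cx * cy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Pairwise Pearson correlation matrix of a cohort table
#'
#' Computes all pairwise sample correlations among the 21 canonical feature
#' columns. In strict mode (default) any missing value or constant feature is
#' an error; with `pairwise_complete = TRUE` each entry is computed over the
#' rows complete for that pair and the per-entry sample size is recorded.
#'
#' @param table A feature table (see [validate_feature_table()]).
#' @param pairwise_complete Logical; opt-in missing-data handling.
#' @return Object of class `ceph_corr`: list with `r` (21 x 21 symmetric
#'   matrix, unit diagonal), `n_used` (matrix of per-entry sample sizes) and
#'   `features`.
#' @export
correlation_matrix <- function(table, pairwise_complete = FALSE) {
  validate_feature_table(table, strict = !pairwise_complete)
  feats <- ceph_features()
  x <- as.matrix(table[, feats, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects to compute correlations")
  p <- length(feats)

  if (!pairwise_complete) {
    sds <- apply(x, 2, stats::sd)
    degen <- feats[sds == 0]
    if (length(degen) > 0) {
      stop("degenerate (constant) feature(s): ", paste(degen, collapse = ", "))
    }
    xc <- scale(x, center = TRUE, scale = FALSE)
    cp <- crossprod(xc)
    d <- sqrt(diag(cp))
    r <- cp / tcrossprod(d)
    n_used <- matrix(n, p, p)
  } else {
    r <- matrix(NA_real_, p, p)
    n_used <- matrix(0L, p, p)
    degen <- character(0)
    for (i in seq_len(p)) {
      r[i, i] <- 1
      n_used[i, i] <- sum(!is.na(x[, i]))
      for (j in seq_len(p)[-seq_len(i)]) {
        ok <- stats::complete.cases(x[, c(i, j)])
        n_ij <- sum(ok)
        n_used[i, j] <- n_used[j, i] <- n_ij
        if (n_ij < 3) {
          stop("fewer than 3 complete pairs for (", feats[i], ", ", feats[j], ")")
        }
        rij <- tryCatch(
          pearson_r(x[ok, i], x[ok, j], feats[i], feats[j]),
          error = function(e) {
            degen <<- unique(c(degen, feats[i], feats[j]))
            NA_real_
          }
        )
        r[i, j] <- r[j, i] <- rij
      }
    }
    if (length(degen) > 0) {
      stop("degenerate (constant) feature(s): ", paste(sort(degen), collapse = ", "))
    }
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(feats, feats)
  dimnames(n_used) <- list(feats, feats)
  structure(list(r = r, n_used = n_used, features = feats), class = "ceph_corr")
}

#' Fisher-z two-sided p-values for a correlation matrix
#'
#' Informational only: edge selection in this package is by correlation
#' magnitude, never by p-value.
#'
#' @param corr A `ceph_corr` object.
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
correlation_pvalues <- function(corr) {
  stopifnot(inherits(corr, "ceph_corr"))
  r <- corr$r
  n <- corr$n_used
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  p <- 2 * stats::pnorm(-abs(z) * sqrt(pmax(n - 3, 0)))
  diag(p) <- NA_real_
  p
}

#' Construct a signed graph
#'
#' Low-level constructor; most users want [threshold_graph()].
#'
#' @param nodes Character node names.
#' @param edges Data frame with columns `from`, `to`, `r` (signed weight).
#' @param cutoff The threshold the edges survived (or `NA`).
#' @return Object of class `signed_graph`.
#' @export
signed_graph <- function(nodes, edges = NULL, cutoff = NA_real_) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        r = as.numeric(edges$r), stringsAsFactors = FALSE)
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad) > 0) stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "))
    if (any(abs(edges$r) > 1 + 1e-12)) stop("edge weights must lie in [-1, 1]")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicated edges")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(nodes), edges = edges, cutoff = cutoff),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("signed_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (!is.na(x$cutoff)) paste0("(|r| > ", x$cutoff, ")") else "", "\n")
  invisible(x)
}

#' Number of edges of a signed graph
#' @param graph A `signed_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Threshold a correlation matrix into a signed graph
#'
#' Two features are linked iff |r| is strictly greater than `cutoff`
#' (default 0.40); an entry of exactly the cutoff yields no edge. Negative
#' correlations are retained with their sign — high negative correlations
#' mark negative-feedback relations and carry as much structure as positive
#' ones. All features stay in the node set even when isolated, so graphs
#' from different strata are comparable over a fixed node set.
#'
#' @param corr A `ceph_corr` object (or plain symmetric correlation matrix
#'   with dimnames).
#' @param cutoff Threshold in \[0, 1).
#' @return A `signed_graph` whose edge weights are the signed correlations.
#' @export
threshold_graph <- function(corr, cutoff = 0.40) {
  if (inherits(corr, "ceph_corr")) {
    r <- corr$r
  } else if (is.matrix(corr)) {
    if (is.null(dimnames(corr)[[1]])) stop("correlation matrix needs dimnames")
    if (max(abs(corr - t(corr))) > 1e-12) stop("correlation matrix is not symmetric")
    r <- corr
  } else {
    stop("corr must be a ceph_corr object or a matrix")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff >= 1) {
    stop("cutoff must lie in [0, 1)")
  }
  feats <- rownames(r)
  idx <- which(upper.tri(r) & abs(r) > cutoff, arr.ind = TRUE)
  edges <- data.frame(
    from = feats[idx[, 1]],
    to = feats[idx[, 2]],
    r = r[idx],
    stringsAsFactors = FALSE
  )
  signed_graph(feats, edges, cutoff = cutoff)
}

# igraph view of the unsigned skeleton; weights preserved as attribute r.
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  )
}

#' Write a correlation matrix as TSV
#'
#' Features x features, full floating-point precision.
#'
#' @param corr A `ceph_corr` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(corr, path) {
  stopifnot(inherits(corr, "ceph_corr"))
  m <- format(corr$r, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- c(
    paste(c("feature", colnames(corr$r)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(corr$r)[i], m[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a signed graph as an edge-list TSV
#'
#' Columns `feature_a`, `feature_b`, `r`.
#'
#' @param graph A `signed_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "signed_graph"))
  lines <- c("feature_a\tfeature_b\tr",
             sprintf("%s\t%s\t%.17g", graph$edges$from, graph$edges$to, graph$edges$r))
  writeLines(lines, path)
  invisible(path)
}

#' Write a signed graph as GraphML
#'
#' Edge attributes `r` (signed correlation, full precision) and `abs_r`.
#' The writer emits plain GraphML readable by igraph, Cytoscape or yEd;
#' weights are serialized with 17 significant digits so a read-back
#' round-trip is exact.
#'
#' @param graph A `signed_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "signed_graph"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  ids <- stats::setNames(sprintf("n%d", seq_along(graph$nodes) - 1L), graph$nodes)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="v_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="e_r" for="edge" attr.name="r" attr.type="double"/>',
    '  <key id="e_abs_r" for="edge" attr.name="abs_r" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"><data key="v_name">%s</data></node>',
            ids, esc(graph$nodes)),
    if (nrow(graph$edges) > 0) {
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="e_r">%.17g</data>',
                     '<data key="e_abs_r">%.17g</data></edge>'),
              ids[graph$edges$from], ids[graph$edges$to],
              graph$edges$r, abs(graph$edges$r))
    },
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed graph from GraphML
#'
#' Inverse of [write_graphml()]; also accepts GraphML written by igraph with
#' a `name` node attribute and an `r` edge attribute.
#'
#' @param path GraphML file.
#' @param cutoff Optional cutoff to record on the graph object.
#' @return A `signed_graph`.
#' @export
read_graphml <- function(path, cutoff = NA_real_) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"), xml2::xml_attr(keys, "id"))
  node_els <- xml2::xml_find_all(doc, ".//graph/node")
  node_ids <- xml2::xml_attr(node_els, "id")
  get_data <- function(el, wanted) {
    data <- xml2::xml_find_all(el, "./data")
    k <- xml2::xml_attr(data, "key")
    hit <- which(key_name[k] == wanted)
    if (length(hit) == 0) NA_character_ else xml2::xml_text(data[[hit[1]]])
  }
  names_attr <- vapply(node_els, get_data, character(1), wanted = "name")
  node_names <- ifelse(is.na(names_attr), node_ids, names_attr)
  lut <- stats::setNames(node_names, node_ids)
  edge_els <- xml2::xml_find_all(doc, ".//graph/edge")
  if (length(edge_els) > 0) {
    edges <- data.frame(
      from = lut[xml2::xml_attr(edge_els, "source")],
      to = lut[xml2::xml_attr(edge_els, "target")],
      r = as.numeric(vapply(edge_els, get_data, character(1), wanted = "r")),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- NULL
  }
  signed_graph(node_names, edges, cutoff = cutoff)
}
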
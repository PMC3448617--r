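# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the code paths they check: components by boolean closure of the
# adjacency matrix, bridges by node deletion and recount, cliques by
# exhaustive subset enumeration.

rand_signed_graph <- function(n, p, nodes = sprintf("N%02d", seq_len(n))) {
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  r <- stats::runif(sum(keep), -1, 1)
  r[r == 0] <- 0.5
  signed_graph(nodes, data.frame(from = pairs[1, keep], to = pairs[2, keep],
                                 r = r, stringsAsFactors = FALSE))
}

graph_from_pairs <- function(nodes, pairs, r = NULL) {
  if (length(pairs) == 0) return(signed_graph(nodes))
  m <- if (is.matrix(pairs)) pairs else matrix(pairs, ncol = 2, byrow = TRUE)
  if (is.null(r)) r <- rep(0.5, nrow(m))
  signed_graph(nodes, data.frame(from = m[, 1], to = m[, 2], r = r,
                                 stringsAsFactors = FALSE))
}

adj_matrix <- function(g) {
  n <- length(g$nodes)
  a <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    a[cbind(g$edges$from, g$edges$to)] <- TRUE
    a <- a | t(a)
  }
  a
}

# components as a canonical list (each sorted; list sorted by first element)
oracle_components_canonical <- function(g) {
  a <- adj_matrix(g)
  diag(a) <- TRUE
  repeat {
    a2 <- (a %*% a) > 0
    if (identical(a2, a)) break
    a <- a2
  }
  ids <- apply(a, 1, function(row) paste(which(row), collapse = ","))
  sets <- lapply(split(g$nodes, ids), sort)
  names(sets) <- NULL
  sets[order(vapply(sets, `[`, character(1), 1))]
}

oracle_component_count <- function(g) length(oracle_components_canonical(g))

drop_node <- function(g, v) {
  keep <- g$edges$from != v & g$edges$to != v
  signed_graph(setdiff(g$nodes, v), g$edges[keep, , drop = FALSE])
}

oracle_bridges <- function(g) {
  base <- oracle_component_count(g)
  hits <- vapply(g$nodes, function(v) {
    oracle_component_count(drop_node(g, v)) > base
  }, logical(1))
  sort(g$nodes[hits])
}

oracle_max_cliques <- function(g, min_size = 3) {
  a <- adj_matrix(g)
  nodes <- g$nodes
  n <- length(nodes)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < min_size) next
    sub <- a[idx, idx, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    outside <- setdiff(seq_len(n), idx)
    if (length(outside) > 0 &&
        any(colSums(a[idx, outside, drop = FALSE]) == length(idx))) next
    out[[length(out) + 1]] <- sort(nodes[idx])
  }
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(-lengths(out), keys)]
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  unname(sets[order(keys)])
}

edge_key_df <- function(df) {
  sort(paste(pmin(df$from, df$to), pmax(df$from, df$to), sep = "\r"))
}

# three planted blocks with no cross structure: the ground-truth world for
# module-recovery checks
planted_block_config <- function(seed, n_per_group = c(G1 = 500, G2 = 500,
                                                       G3 = 500, G4 = 500)) {
  synthetic_config(
    n_per_group = n_per_group,
    blocks = list(
      block_spec("mandibular-sagittal", c("SNB", "Co-Gn", "Go-Pg"), 0.7),
      block_spec("maxillomandibular-divergence", c("NS-GoGn", "PP-PM", "NMe"), 0.7),
      block_spec("adaptive-dentoalveolar",
                 c("IMPA", "FMIA", "Interincisal", "Overjet"), 0.7)
    ),
    background_r = 0,
    seed = seed
  )
}

planted_block_sets <- function(config) {
  canonical_sets(lapply(config$blocks, `[[`, "members"))
}
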
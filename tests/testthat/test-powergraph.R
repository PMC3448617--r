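test_that("maximal_cliques finds the canonical cases", {
  tri <- graph_from_pairs(c("A", "B", "C"), c("A", "B", "B", "C", "A", "C"))
  expect_equal(maximal_cliques(tri), list(c("A", "B", "C")))

  path4 <- graph_from_pairs(LETTERS[1:4], c("A", "B", "B", "C", "C", "D"))
  expect_equal(maximal_cliques(path4, min_size = 3), list())
  expect_equal(length(maximal_cliques(path4, min_size = 2)), 3)

  expect_equal(maximal_cliques(signed_graph(LETTERS[1:4])), list())
})

test_that("maximal_cliques equals the exhaustive subset oracle", {
  set.seed(31)
  for (i in 1:25) {
    g <- rand_signed_graph(sample(4:9, 1), runif(1, 0.2, 0.9))
    for (ms in c(2, 3)) {
      expect_equal(maximal_cliques(g, min_size = ms),
                   oracle_max_cliques(g, min_size = ms))
    }
  }
})

test_that("K4 compresses to a single clique power edge", {
  k4 <- graph_from_pairs(LETTERS[1:4], t(utils::combn(LETTERS[1:4], 2)))
  pg <- power_decompose(k4)
  expect_equal(nrow(pg$power_edges), 1)
  expect_equal(pg$power_edges$kind, "clique")
  expect_equal(sort(pg$power_nodes[[pg$power_edges$a]]), LETTERS[1:4])
  expect_equal(nrow(pg$residual_edges), 0)
  mr <- module_report(pg)
  expect_equal(mr$compression_ratio, 6)  # 6 edges -> 1 power edge
})

test_that("K2,3 compresses to one biclique power edge", {
  left <- c("A", "B"); right <- c("X", "Y", "Z")
  prs <- expand.grid(a = left, b = right, stringsAsFactors = FALSE)
  g <- graph_from_pairs(c(left, right),
                        as.vector(t(as.matrix(prs))))
  pg <- power_decompose(g)
  expect_equal(nrow(pg$power_edges), 1)
  expect_equal(pg$power_edges$kind, "biclique")
  sides <- canonical_sets(list(pg$power_nodes[[pg$power_edges$a]],
                               pg$power_nodes[[pg$power_edges$b]]))
  expect_equal(sides, canonical_sets(list(left, right)))
  expect_equal(nrow(pg$residual_edges), 0)
})

test_that("decomposition of an empty graph is empty with NA ratio", {
  pg <- power_decompose(signed_graph(ceph_features()))
  expect_equal(length(pg$power_nodes), 0)
  mr <- module_report(pg)
  expect_equal(nrow(mr$modules), 0)
  expect_true(is.na(mr$compression_ratio))
})

test_that("expansion reproduces the source edge set exactly", {
  set.seed(32)
  for (i in 1:40) {
    g <- rand_signed_graph(sample(3:12, 1), runif(1, 0.05, 0.95))
    pg <- power_decompose(g)
    expect_identical(edge_key_df(expand_power_graph(pg)),
                     edge_key_df(g$edges))
    # power node sets pairwise disjoint or nested, never partially overlapping
    pn <- pg$power_nodes
    if (length(pn) > 1) {
      for (a in seq_along(pn)) for (b in seq_len(a - 1)) {
        k <- length(intersect(pn[[a]], pn[[b]]))
        expect_true(k == 0 || k == length(pn[[a]]) || k == length(pn[[b]]))
      }
    }
  }
})

test_that("decomposition is deterministic", {
  set.seed(33)
  g <- rand_signed_graph(12, 0.4)
  pg1 <- power_decompose(g)
  pg2 <- power_decompose(g)
  expect_identical(pg1$power_nodes, pg2$power_nodes)
  expect_identical(pg1$power_edges, pg2$power_edges)
  expect_identical(pg1$residual_edges, pg2$residual_edges)
})

test_that("a planted 3-block cohort yields exactly the planted clique modules", {
  cfg <- planted_block_config(seed = 34)
  tab <- simulate_cohort(cfg)
  g <- threshold_graph(correlation_matrix(tab), cutoff = 0.40)
  pg <- power_decompose(g)
  expect_equal(pg$power_edges$kind, rep("clique", 3))
  found <- canonical_sets(lapply(pg$power_edges$a, function(id) pg$power_nodes[[id]]))
  expect_equal(found, planted_block_sets(cfg))
  expect_equal(nrow(pg$residual_edges), 0)
})

test_that("module_report summarizes sign mix and category composition", {
  cfg <- planted_block_config(seed = 35)
  tab <- simulate_cohort(cfg)
  g <- threshold_graph(correlation_matrix(tab), cutoff = 0.40)
  pg <- power_decompose(g)
  labels <- c(SNB = "structural", `Co-Gn` = "structural", `Go-Pg` = "structural",
              `NS-GoGn` = "structural", `PP-PM` = "structural", NMe = "structural",
              IMPA = "adaptive", FMIA = "adaptive", Interincisal = "adaptive",
              Overjet = "adaptive")
  mr <- module_report(pg, labels = labels)
  expect_equal(nrow(mr$modules), 3)
  expect_true(all(mr$modules$mean_abs_r > 0.4))
  expect_true(all(mr$modules$n_positive + mr$modules$n_negative ==
                  mr$modules$covered_edges))
  adaptive <- mr$modules[grepl("IMPA", mr$modules$members), ]
  expect_equal(adaptive$categories, "adaptive:4")
  expect_warning(module_report(pg, labels = c(Nope = "x")), "unknown")
})

test_that("power graph GraphML carries power_node_id and edge kinds", {
  k4 <- graph_from_pairs(LETTERS[1:4], t(utils::combn(LETTERS[1:4], 2)))
  pg <- power_decompose(k4)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_power_graphml(pg, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  kinds <- xml2::xml_text(xml2::xml_find_all(doc, '//edge/data[@key="e_kind"]'))
  expect_equal(kinds, rep("clique", 6))
  pns <- xml2::xml_text(xml2::xml_find_all(doc, '//node/data[@key="v_pn"]'))
  expect_equal(pns, rep("P1", 4))
})
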
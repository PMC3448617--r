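test_that("pearson_r matches the analytic formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # frozen hand-computed value: centered cross product 10, sums of squares
  # 10 and 14.8, so r = 10 / sqrt(148)
  expect_equal(pearson_r(1:5, c(2, 1, 4, 3, 6)), 10 / sqrt(148),
               tolerance = 1e-12)
})

test_that("pearson_r rejects degenerate input and names the feature", {
  expect_error(pearson_r(1:4, 1:5), "length mismatch")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5, x_name = "SNA"), "SNA")
  expect_error(pearson_r(1:5, rep(2, 5), y_name = "IMPA"), "IMPA")
})

test_that("pearson_r is affine-invariant up to sign", {
  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    r <- pearson_r(x, y)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(-a * x + b, y), -r, tolerance = 1e-12)
  }
})

test_that("correlation_matrix is symmetric with unit diagonal", {
  tab <- simulate_cohort(default_synthetic_config(
    seed = 3, n_per_group = c(G1 = 30, G2 = 10, G3 = 10, G4 = 10)))
  cm <- correlation_matrix(tab)
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 21))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  expect_true(all(cm$n_used == nrow(tab)))
  # identical columns correlate at exactly 1
  tab2 <- tab
  tab2$SN <- tab2$`Co-A`
  expect_equal(correlation_matrix(tab2)$r["SN", "Co-A"], 1.0)
})

test_that("correlation_matrix reports degenerate and missing features", {
  tab <- simulate_cohort(default_synthetic_config(
    seed = 4, n_per_group = c(G1 = 10, G2 = 10, G3 = 10, G4 = 10)))
  tab$SNA <- 80
  expect_error(correlation_matrix(tab), "SNA")
  tab$SNA <- rnorm(40)
  tab$IMPA[3] <- NA
  expect_error(correlation_matrix(tab), "missing")
  # pairwise-complete mode computes over complete pairs and records n_used
  cm <- correlation_matrix(tab, pairwise_complete = TRUE)
  expect_equal(cm$n_used["IMPA", "SN"], 39L)
  expect_equal(cm$n_used["SN", "Wits"], 40L)
  ok <- !is.na(tab$IMPA)
  expect_equal(cm$r["IMPA", "SN"], pearson_r(tab$IMPA[ok], tab$SN[ok]))
})

test_that("thresholding is strict and keeps negative correlations", {
  feats <- c("A", "B", "C", "D")
  m <- diag(4); dimnames(m) <- list(feats, feats)
  m["A", "B"] <- m["B", "A"] <- 0.40      # exactly at cutoff: no edge
  m["A", "C"] <- m["C", "A"] <- -0.55     # negative, above cutoff in magnitude
  m["B", "C"] <- m["C", "B"] <- 0.41
  g <- threshold_graph(m, cutoff = 0.40)
  ek <- edge_key_df(g$edges)
  expect_false("A\rB" %in% ek)
  expect_setequal(ek, c("A\rC", "B\rC"))
  expect_equal(g$edges$r[g$edges$from == "A" & g$edges$to == "C"], -0.55)
  expect_setequal(g$nodes, feats)  # isolated D retained
  expect_error(threshold_graph(m, cutoff = 1), "cutoff")
  expect_error(threshold_graph(m, cutoff = -0.1), "cutoff")
})

test_that("edge sets shrink monotonically and nest as the cutoff grows", {
  tab <- simulate_cohort(default_synthetic_config(
    seed = 6, n_per_group = c(G1 = 20, G2 = 20, G3 = 20, G4 = 20)))
  cm <- correlation_matrix(tab)
  cuts <- c(0, 0.2, 0.4, 0.6, 0.8)
  graphs <- lapply(cuts, function(ct) threshold_graph(cm, cutoff = ct))
  counts <- vapply(graphs, n_edges, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], choose(21, 2))  # cutoff 0: complete graph
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(edge_key_df(graphs[[i]]$edges) %in%
                    edge_key_df(graphs[[i - 1]]$edges)))
  }
})

test_that("GraphML round-trips nodes, edges and weights exactly", {
  set.seed(77)
  g <- rand_signed_graph(12, 0.35)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  g2 <- read_graphml(path, cutoff = g$cutoff)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)
  # file is also readable by igraph as an independent parser
  ig <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(ig)$name, g$nodes)
  expect_equal(igraph::ecount(ig), n_edges(g))
})

test_that("correlation_pvalues is informational and sane", {
  tab <- simulate_cohort(planted_block_config(
    seed = 8, n_per_group = c(G1 = 100, G2 = 100, G3 = 100, G4 = 100)))
  cm <- correlation_matrix(tab)
  p <- correlation_pvalues(cm)
  expect_true(all(is.na(diag(p))))
  off <- p[upper.tri(p)]
  expect_true(all(off >= 0 & off <= 1))
  expect_lt(p["SNB", "Co-Gn"], 1e-6)   # planted 0.7 at n = 400
})
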
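test_that("build_target_correlation places blocks, links and background", {
  cfg0 <- synthetic_config(seed = 1)
  expect_equal(build_target_correlation(cfg0),
               diag(21) |> `dimnames<-`(list(ceph_features(), ceph_features())))

  cfg <- synthetic_config(
    blocks = list(block_spec("b", c("SN", "Co-A", "Co-Gn"), 0.7)),
    cross_links = list(cross_link("NMe", "IMPA", -0.5)),
    background_r = 0.1, seed = 1
  )
  m <- build_target_correlation(cfg)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 21))
  expect_equal(m["SN", "Co-A"], 0.7)
  expect_equal(m["Co-A", "Co-Gn"], 0.7)
  expect_equal(m["NMe", "IMPA"], -0.5)
  expect_equal(m["IMPA", "NMe"], -0.5)
  expect_equal(m["SN", "Wits"], 0.1)
})

test_that("conflicting configurations are rejected", {
  expect_error(
    build_target_correlation(synthetic_config(blocks = list(
      block_spec("a", c("SN", "Co-A"), 0.5),
      block_spec("b", c("Co-A", "Co-Gn"), 0.5)
    ), seed = 1)),
    "overlap"
  )
  expect_error(
    build_target_correlation(synthetic_config(
      blocks = list(block_spec("a", c("SN", "Co-A"), 0.5)),
      cross_links = list(cross_link("SN", "Co-A", -0.3)), seed = 1
    )),
    "conflicts"
  )
  expect_error(block_spec("b", c("SN", "NotAFeature"), 0.5), "unknown")
  expect_error(block_spec("b", character(0), 0.5), "no members")
  expect_error(cross_link("SN", "SN", 0.5), "differ")
  expect_error(synthetic_config(n_per_group = c(G1 = 0, G2 = 1, G3 = 1, G4 = 1)),
               "positive")
})

test_that("nearest_psd fixes indefinite matrices and leaves PSD ones alone", {
  expect_equal(nearest_psd(diag(3)), diag(3))

  blk <- matrix(0.7, 3, 3); diag(blk) <- 1
  expect_equal(nearest_psd(blk), blk)

  # indefinite by construction: min eigenvalue -0.8
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_lt(min(eigen(bad, symmetric = TRUE, only.values = TRUE)$values), 0)
  fixed <- nearest_psd(bad)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(unname(diag(fixed)), rep(1, 3))
  expect_equal(fixed, t(fixed))
  # idempotence
  expect_equal(nearest_psd(fixed), fixed, tolerance = 1e-10)

  expect_error(nearest_psd(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("simulate_cohort reproduces the stated cohort design", {
  tab <- simulate_cohort(default_synthetic_config(seed = 11))
  expect_equal(nrow(tab), 532)
  expect_equal(as.vector(table(factor(tab$group, c("G1", "G2", "G3", "G4")))),
               c(240, 89, 105, 98))
  expect_true(all(ceph_features() %in% names(tab)))
  # ages stay inside their group brackets
  br <- default_age_groups()
  for (i in seq_len(nrow(br))) {
    a <- tab$age[tab$group == br$name[i]]
    expect_true(all(a >= br$lower[i] & a < br$upper[i]))
  }
})

test_that("generation is deterministic in the seed", {
  cfg <- default_synthetic_config(seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- default_synthetic_config(seed = 43)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("planted correlations and marginals are recovered at large n", {
  cfg <- planted_block_config(seed = 5)
  tab <- simulate_cohort(cfg)           # n = 2000
  n <- nrow(tab)
  r <- correlation_matrix(tab)$r
  tol <- 3 / sqrt(n)
  for (b in cfg$blocks) {
    prs <- utils::combn(b$members, 2)
    for (k in seq_len(ncol(prs))) {
      expect_lt(abs(r[prs[1, k], prs[2, k]] - 0.7), tol)
    }
  }
  # a background pair stays near zero
  expect_lt(abs(r["SN", "Wits"]), tol)
  # marginals converge to configuration
  for (f in c("SNB", "Wits", "NMe")) {
    expect_lt(abs(mean(tab[[f]]) - cfg$feature_means[[f]]),
              4 * cfg$feature_sds[[f]] / sqrt(n))
    expect_lt(abs(sd(tab[[f]]) - cfg$feature_sds[[f]]),
              4 * cfg$feature_sds[[f]] / sqrt(n))
  }
})
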
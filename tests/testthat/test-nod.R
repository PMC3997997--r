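test_that("NOD counts genes with exactly one regulator", {
  db <- db_from_edges(data.frame(mirna = c("m1", "m1", "m2", "m2"),
                                 gene = c("G1", "G2", "G2", "G3"),
                                 stringsAsFactors = FALSE))
  nod <- compute_nod(db)
  expect_equal(nod$nod[nod$mirna == "m1"], 1L)   # G2 is shared
  expect_equal(nod$nod[nod$mirna == "m2"], 1L)
  expect_equal(exclusive_targets(nod)[["m1"]], "G1")

  solo <- db_from_edges(data.frame(mirna = "m1", gene = c("G1", "G2", "G3"),
                                   stringsAsFactors = FALSE))
  expect_equal(compute_nod(solo)$nod, 3L)
})

test_that("NOD equals a brute-force regulator recount on random graphs", {
  for (seed in 1:20) {
    edges <- random_bipartite(50, 300, 0.02, seed)
    nod <- compute_nod(db_from_edges(edges))
    oracle <- brute_nod(edges)
    expect_equal(stats::setNames(nod$nod, nod$mirna), oracle[nod$mirna])
    # conservation: NODs sum to the number of single-regulator genes
    expect_equal(sum(nod$nod), sum(table(edges$gene) == 1L))
    # exclusive sets are pairwise disjoint
    ex <- exclusive_targets(nod)
    expect_equal(length(unlist(ex)), length(unique(unlist(ex))))
  }
})

test_that("adding an edge only ever removes exclusivity from its gene's owner", {
  edges <- random_bipartite(20, 100, 0.04, 5)
  db <- db_from_edges(edges)
  nod <- compute_nod(db)
  ex <- exclusive_targets(nod)
  owner <- names(which(lengths(ex) > 0))[1L]
  g <- ex[[owner]][1L]
  other <- setdiff(unique(edges$mirna), owner)[1L]
  nod2 <- compute_nod(db_from_edges(rbind(edges,
    data.frame(mirna = other, gene = g, stringsAsFactors = FALSE))))
  n1 <- stats::setNames(nod$nod, nod$mirna)
  n2 <- stats::setNames(nod2$nod, nod2$mirna)
  expect_equal(n2[[owner]], n1[[owner]] - 1L)
  expect_true(all(n2[names(n1)] <= n1))
})

test_that("signed-rank NOD significance matches exact enumeration at small n", {
  set.seed(1)
  for (i in 1:10) {
    # ties-free |d|: the exact signed-rank null applies
    d <- sample(1:12, 9) * sample(c(-1, 1), 9, replace = TRUE)
    expect_equal(mirnod:::signed_rank_greater(d), enum_signed_rank_greater(d),
                 tolerance = 1e-12)
  }
  for (i in 1:5) {
    # tied |d|: the corrected normal approximation tracks the enumeration
    d <- sample(1:5, 10, replace = TRUE) * sample(c(-1, 1), 10, replace = TRUE)
    expect_lt(abs(mirnod:::signed_rank_greater(d) - enum_signed_rank_greater(d)),
              0.05)
  }
  # focal strictly above all others: minimal one-sided P = 1/2^n
  nods <- stats::setNames(c(50, sample(1:30, 12)), c("top", sprintf("m%d", 1:12)))
  nods_d <- nods[["top"]] - nods[-1L]
  if (!anyDuplicated(abs(nods_d))) {
    expect_equal(nod_significance(nods, "top"), 1 / 2^12, tolerance = 1e-12)
  }
  expect_equal(nod_significance(stats::setNames(c(50, 1:12), c("t", letters[1:12])), "t"),
               psignrank(12 * 13 / 2 - 1, 12, lower.tail = FALSE))
})

test_that("signed-rank significance agrees with wilcox.test on continuous data", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(c(8, 15, 40), 1)
    d <- rnorm(n) + 0.3
    ours <- mirnod:::signed_rank_greater(d)
    ref <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = "greater",
                  exact = n <= 25, correct = TRUE))
    expect_equal(ours, ref$p.value, tolerance = 1e-8)
  }
})

test_that("NOD significance is one-sided, calibrated at the median, and monotone", {
  # focal smallest of 3: no evidence of exceeding the median
  expect_gte(nod_significance(c(a = 1, b = 5, c = 9), "a"), 0.5)

  # focal at the centre of a symmetric population: p near 0.5
  set.seed(3)
  ps <- replicate(50, {
    pop <- round(rnorm(60, 50, 10))
    nods <- stats::setNames(c(50, pop), c("f", sprintf("m%d", 1:60)))
    nod_significance(nods, "f")
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)

  # raising the focal NOD never raises the p-value
  pop <- stats::setNames(sample(0:20, 30, replace = TRUE), sprintf("m%d", 1:30))
  ps <- vapply(c(0, 5, 10, 20, 40), function(v) {
    nod_significance(c(pop, f = v), "f")
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # degenerate: all differences zero
  expect_equal(nod_significance(c(a = 3, b = 3, c = 3), "a"), 0.5)
  expect_error(nod_significance(c(a = 1, b = 2, c = 3), "zz"), "zz")
})

test_that("K-S comparison separates shifted NOD distributions", {
  same <- compare_nod_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$ks_stat, 0)
  expect_equal(same$ks_p, 1)
  expect_equal(compare_nod_distributions(c(10, 10, 10), c(0, 0, 0))$ks_stat, 1)
  expect_error(compare_nod_distributions(numeric(), 1:3), "non-empty")

  set.seed(4)
  ks_p <- replicate(100, {
    pop <- rpois(600, 3)
    grp <- rpois(10, 3) + 5
    compare_nod_distributions(grp, pop)$ks_p
  })
  expect_lt(median(ks_p), 0.05)
})

test_that("candidates are ranked NOD-descending with deterministic tie-breaks", {
  de <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                   t_stat = 1, p_value = c(0.01, 0.02, 0.001, 0.002),
                   p_bh = 1, fc_linear = 2.5, fc_log2 = 1.3,
                   zero_variance = FALSE, candidate = TRUE,
                   stringsAsFactors = FALSE)
  nods <- data.frame(mirna = c("m1", "m2", "m3", "m4", sprintf("x%d", 1:30)),
                     nod = c(9L, 14L, 9L, 2L, rep(0L, 30)),
                     stringsAsFactors = FALSE)
  rk <- rank_candidates_by_nod(de, nods, alpha_nod = 1)
  expect_equal(rk$mirna, c("m2", "m3", "m1", "m4"))  # tie m1/m3 broken by p
  expect_true(all(rk$retained))                      # alpha_nod = 1 keeps all

  # a candidate absent from the database is kept with nod 0 and flagged
  de2 <- rbind(de, data.frame(mirna = "ghost", t_stat = 1, p_value = 0.04,
                              p_bh = 1, fc_linear = 2.1, fc_log2 = 1.1,
                              zero_variance = FALSE, candidate = TRUE))
  rk2 <- rank_candidates_by_nod(de2, nods, alpha_nod = 1)
  expect_false(rk2$in_db[rk2$mirna == "ghost"])
  expect_equal(rk2$nod[rk2$mirna == "ghost"], 0L)

  # both reference populations are supported
  rk_db <- rank_candidates_by_nod(de, nods, reference = "db")
  rk_cand <- rank_candidates_by_nod(de, nods, reference = "candidates")
  expect_equal(rk_db$mirna, rk_cand$mirna)
  # against the sparse full DB a NOD of 14 is extreme; among the four
  # candidates it is not
  expect_lt(rk_db$nod_p[rk_db$mirna == "m2"], rk_cand$nod_p[rk_cand$mirna == "m2"])
})
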
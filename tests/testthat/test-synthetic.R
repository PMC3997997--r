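test_that("exclusivity limits behave as designed", {
  # every target exclusive: NOD equals out-degree
  net1 <- sim_interaction_network(n_mirnas = 10, n_genes = 200, mean_targets = 6,
                                  exclusive_fraction = 1, seed = 41)
  db1 <- build_interaction_db(net1$validated, net1$predicted)
  nod1 <- compute_nod(db1)
  deg <- lengths(db1$mirna_index)
  expect_equal(stats::setNames(nod1$nod, nod1$mirna), deg[nod1$mirna])

  # no exclusive targets: every gene has >= 2 regulators, all NOD zero
  net0 <- sim_interaction_network(n_mirnas = 10, n_genes = 60, mean_targets = 6,
                                  exclusive_fraction = 0, seed = 42)
  db0 <- build_interaction_db(net0$validated, net0$predicted)
  expect_true(all(lengths(db0$gene_index) >= 2L))
  expect_true(all(compute_nod(db0)$nod == 0L))
})

test_that("the generated source tables reconstruct the intended network exactly", {
  for (seed in c(1, 7, 23)) {
    net <- sim_interaction_network(n_mirnas = 30, n_genes = 250, mean_targets = 8,
                                   exclusive_fraction = 0.3,
                                   hub_boost = c(`hsa-mir-s0001` = 20L),
                                   n_decoy = 40, seed = seed)
    db <- build_interaction_db(net$validated, net$predicted)
    expect_equal(db$edges[, c("mirna", "gene")], net$truth$edges)
    nod <- compute_nod(db)
    expect_equal(stats::setNames(nod$nod, nod$mirna),
                 net$truth$planted_nod[nod$mirna])
    expect_equal(summary(db)$n_edges, net$truth$n_edges)
    # decoys really are single-source predictions
    pred_keys <- unlist(lapply(net$predicted, function(x) paste(x$mirna, x$gene)))
    decoy_keys <- setdiff(pred_keys, paste(net$truth$edges$mirna, net$truth$edges$gene))
    if (length(decoy_keys)) {
      expect_true(all(table(pred_keys[pred_keys %in% decoy_keys]) == 1L))
    }
  }
  expect_error(sim_interaction_network(n_mirnas = 10, n_genes = 20,
                                       mean_targets = 10,
                                       exclusive_fraction = 1, seed = 1),
               "exceed")
})

test_that("expression generation is reproducible and plants real effects", {
  a <- sim_expression(n_mirnas = 50, seed = 50)
  b <- sim_expression(n_mirnas = 50, seed = 50)
  expect_identical(a$eset$values, b$eset$values)
  c2 <- sim_expression(n_mirnas = 50, seed = 51)
  expect_false(identical(a$eset$values, c2$eset$values))

  planted <- data.frame(mirna = sprintf("hsa-mir-s%04d", 1:6),
                        direction = rep(c("up", "down"), 3), effect = 4,
                        stringsAsFactors = FALSE)
  sim <- sim_expression(n_mirnas = 60, planted = planted, noise_sd = 0.3,
                        seed = 7)
  de <- de_candidates(sim$eset)
  hit <- de[de$mirna %in% planted$mirna, ]
  expect_true(all(hit$p_value < 0.05 & abs(hit$fc_linear) >= 2))
  up <- planted$mirna[planted$direction == "up"]
  expect_true(all(hit$fc_linear[hit$mirna %in% up] > 0))
  expect_true(all(hit$fc_linear[!hit$mirna %in% up] < 0))

  expect_error(sim_expression(planted = planted[c(1, 1), ], seed = 1),
               "duplicate")
  expect_error(sim_expression(planted = transform(planted, effect = -1), seed = 1),
               "> 0")
})

test_that("null matrices give calibrated type-I error", {
  null_p <- unlist(lapply(1:20, function(s) {
    sim <- sim_expression(n_mirnas = 200, seed = 500 + s)
    de_candidates(sim$eset, fc_threshold = 0)$p_value
  }))
  n <- length(null_p)
  hits <- sum(null_p < 0.05)
  expect_gte(hits, qbinom(0.005, n, 0.05))
  expect_lte(hits, qbinom(0.995, n, 0.05))
})

test_that("synthetic PPI graphs hit the requested density", {
  genes <- sprintf("G%04d", 1:200)
  mean_deg <- vapply(1:20, function(s) {
    g <- sim_ppi(genes, mean_degree = 5, seed = s)$graph
    mean(igraph::degree(g))
  }, numeric(1))
  expect_lt(abs(mean(mean_deg) - 5) / 5, 0.1)

  g1 <- sim_ppi(genes, mean_degree = 4, seed = 3)$graph
  g2 <- sim_ppi(genes, mean_degree = 4, seed = 3)$graph
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  sf <- sim_ppi(genes, mean_degree = 4, model = "scale_free", seed = 3)$graph
  expect_true(igraph::is_simple(sf))
  expect_error(sim_ppi(genes[1:3], mean_degree = 10, seed = 1), "mean_degree")
})

test_that("generated GMT files are valid and the planted set is null at OR=1", {
  universe <- sprintf("G%03d", 1:100)
  gs <- sim_gene_sets(universe, n_sets = 12, planted_genes = universe[1:20],
                      odds_ratio = 1, seed = 61)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs$collection, path)
  lines <- readLines(path)
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3L))

  # odds ratio 1: no planted signal, so the planted set's P values are
  # exchangeable with the other sets' (two-sample comparison respects the
  # discreteness of hypergeometric P values)
  planted_p <- numeric(); other_p <- numeric()
  for (s in 1:60) {
    g <- sim_gene_sets(universe, n_sets = 12, planted_genes = universe[1:20],
                       odds_ratio = 1, seed = 600 + s)
    r <- hypergeom_enrich(universe[1:20], g$collection)
    planted_p <- c(planted_p, r$p_value[r$set_id == g$truth$planted_set])
    other_p <- c(other_p, r$p_value[r$set_id != g$truth$planted_set])
  }
  expect_gt(suppressWarnings(ks.test(planted_p, other_p))$p.value, 0.01)
})

test_that("bundles are written complete and internally consistent", {
  dir <- withr::local_tempdir()
  b <- sim_bundle(dir, seed = 9, n_mirnas = 40, n_genes = 400,
                  n_expr_mirnas = 35, mean_targets = 10,
                  exclusive_fraction = 0.2, n_planted = 4, n_sets = 10)
  expect_true(all(file.exists(file.path(dir, c("expression.tsv", "labels.tsv",
                                               "ppi.tsv", "pathways.gmt",
                                               "disease.gmt", "truth.json",
                                               "config.yaml")))))
  cfg <- validate_config(file.path(dir, "config.yaml"))
  tabs <- lapply(cfg$sources, function(s) read_interaction_table(s$path, s$name, s$evidence))
  evid <- vapply(cfg$sources, `[[`, "", "evidence")
  db <- build_interaction_db(tabs[evid == "validated"], tabs[evid == "predicted"])
  nod <- compute_nod(db)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  for (m in names(truth$planted_nod)) {
    expect_equal(nod$nod[nod$mirna == m], truth$planted_nod[[m]])
  }
  g <- read_ppi(file.path(dir, "ppi.tsv"))
  expect_equal(igraph::ecount(g), truth$ppi_n_edges)
})
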
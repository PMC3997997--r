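test_that("source tables are parsed, normalized and deduplicated", {
  p <- write_tsv_lines(c("# comment", "hsa-miR-16\tBCL2", "hsa-miR-16\tbcl2"))
  rec <- read_interaction_table(p, "toy", "validated")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mirna, "hsa-mir-16")
  expect_equal(rec$gene, "BCL2")

  empty <- write_tsv_lines("mirna\tgene")
  expect_equal(nrow(read_interaction_table(empty, "toy", "validated",
                                           header = TRUE)), 0L)

  p3 <- write_tsv_lines(c("hsa-miR-1\tGA", "hsa-miR-1\tGB", "hsa-miR-2\tGC"))
  rec3 <- read_interaction_table(p3, "toy", "predicted")
  expect_equal(rec3[, c("mirna", "gene")],
               data.frame(mirna = c("hsa-mir-1", "hsa-mir-1", "hsa-mir-2"),
                          gene = c("GA", "GB", "GC"),
                          stringsAsFactors = FALSE))

  bad <- write_tsv_lines(c("hsa-miR-1\tGA", "lonelyfield"))
  expect_error(read_interaction_table(bad, "toy", "validated"), "line 2")
  expect_error(read_interaction_table(file.path(tempdir(), "nope.tsv"),
                                      "toy", "validated"), "not found")
})

test_that("union rule: validated suffices, predictions need 2 distinct sources", {
  val <- list(make_records(list(c("m1", "G1")), "val_a", "validated"))
  prd <- list(make_records(list(c("m2", "G2"), c("m3", "G3")), "pred_a", "predicted"),
              make_records(list(c("m3", "G3")), "pred_b", "predicted"))
  db <- build_interaction_db(val, prd)
  keys <- paste(db$edges$mirna, db$edges$gene)
  expect_true("m1 G1" %in% keys)    # one validated source is enough
  expect_false("m2 G2" %in% keys)   # one predicted source is not
  expect_true("m3 G3" %in% keys)    # two distinct predicted sources
  expect_error(build_interaction_db(val, prd, min_predicted_support = 0),
               "min_predicted_support")
})

test_that("union build matches brute-force set algebra on random toy tables", {
  for (seed in 1:5) {
    set.seed(seed)
    pool <- expand.grid(mirna = sprintf("m%d", 1:6), gene = sprintf("G%d", 1:10),
                        stringsAsFactors = FALSE)
    draw <- function() pool[sample(nrow(pool), 12), ]
    val <- lapply(1:3, function(i)
      data.frame(draw(), source = paste0("v", i), evidence = "validated",
                 stringsAsFactors = FALSE))
    prd <- lapply(1:3, function(i)
      data.frame(draw(), source = paste0("p", i), evidence = "predicted",
                 stringsAsFactors = FALSE))
    db <- build_interaction_db(val, prd)
    # oracle: validated union + predicted pairs in >= 2 distinct sources
    vkeys <- unique(unlist(lapply(val, function(x) paste(x$mirna, x$gene))))
    pkeys <- unlist(lapply(prd, function(x) unique(paste(x$mirna, x$gene))))
    expect_setequal(paste(db$edges$mirna, db$edges$gene),
                    union(vkeys, names(table(pkeys))[table(pkeys) >= 2]))
  }
})

test_that("database summary counts edges, miRNAs and genes", {
  empty <- build_interaction_db()
  expect_equal(unclass(summary(empty))[],
               list(n_edges = 0L, n_mirnas = 0L, n_genes = 0L))

  val <- list(make_records(list(c("m1", "G1"), c("m1", "G2"), c("m1", "G3"),
                                c("m2", "G3"), c("m2", "G4")),
                           "v", "validated"))
  s <- summary(build_interaction_db(val))
  expect_equal(s$n_edges, 5L)
  expect_equal(s$n_mirnas, 2L)
  expect_equal(s$n_genes, 4L)

  # 10 rows with 3 duplicated pairs collapse to 7 edges
  rows <- list(c("m1", "G1"), c("m1", "G2"), c("m1", "G3"), c("m1", "G1"),
               c("m2", "G1"), c("m2", "G2"), c("m2", "G2"), c("m3", "G1"),
               c("m3", "G3"), c("m3", "G3"))
  p <- write_tsv_lines(vapply(rows, paste, "", collapse = "\t"))
  db <- build_interaction_db(list(read_interaction_table(p, "v", "validated")))
  expect_equal(summary(db)$n_edges, 7L)
})

test_that("indices are exact transposes and provenance is non-empty", {
  net <- sim_interaction_network(n_mirnas = 15, n_genes = 80, mean_targets = 6,
                                 exclusive_fraction = 0.3, n_decoy = 10,
                                 seed = 11)
  db <- build_interaction_db(net$validated, net$predicted)
  for (i in seq_len(nrow(db$edges))) {
    m <- db$edges$mirna[i]; g <- db$edges$gene[i]
    expect_true(g %in% db$mirna_index[[m]])
    expect_true(m %in% db$gene_index[[g]])
  }
  expect_equal(sum(lengths(db$mirna_index)), nrow(db$edges))
  expect_equal(sum(lengths(db$gene_index)), nrow(db$edges))
  expect_true(all(nzchar(db$edges$sources)))
  expect_true(all(db$edges$n_validated_sources + db$edges$n_predicted_sources >= 1))
})

test_that("consensus support is monotone and validated tables dominate", {
  net <- sim_interaction_network(n_mirnas = 12, n_genes = 60, mean_targets = 5,
                                 exclusive_fraction = 0.4, seed = 3)
  key <- function(db) paste(db$edges$mirna, db$edges$gene)
  k1 <- key(build_interaction_db(net$validated, net$predicted, 1))
  k2 <- key(build_interaction_db(net$validated, net$predicted, 2))
  k3 <- key(build_interaction_db(net$validated, net$predicted, 3))
  expect_true(all(k3 %in% k2))
  expect_true(all(k2 %in% k1))
  novalidated <- key(build_interaction_db(list(), net$predicted, 1))
  allpred <- unique(unlist(lapply(net$predicted, function(x) paste(x$mirna, x$gene))))
  expect_setequal(novalidated, allpred)
})

test_that("the union database round-trips through its TSV writer", {
  net <- sim_interaction_network(n_mirnas = 10, n_genes = 50, seed = 7)
  db <- build_interaction_db(net$validated, net$predicted)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_db(db, p)
  db2 <- read_interaction_db(p)
  expect_identical(db$edges, db2$edges)
  expect_identical(db$mirna_index, db2$mirna_index)
})
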
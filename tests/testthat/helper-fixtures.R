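# Shared fixture builders and independent oracles.

# record table in the shape read_interaction_table() returns
make_records <- function(pairs, source, evidence) {
  data.frame(mirna = vapply(pairs, `[[`, "", 1L),
             gene = vapply(pairs, `[[`, "", 2L),
             source = source, evidence = evidence,
             stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force NOD oracle: recount regulators per gene over the edge list
brute_nod <- function(edges) {
  reg <- table(edges$gene)
  excl <- names(reg)[reg == 1L]
  counts <- table(edges$mirna[edges$gene %in% excl])
  out <- stats::setNames(integer(length(unique(edges$mirna))),
                         sort(unique(edges$mirna)))
  out[names(counts)] <- as.integer(counts)
  out
}

# brute-force AUC oracle: mean over all case-control pairs
brute_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) for (y in control_scores) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(case_scores) * length(control_scores))
}

# exact one-sided signed-rank oracle: enumerate all sign assignments
# (ties-free |d| assumed; feasible for n <= 12)
enum_signed_rank_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1L, function(s) sum(r[unlist(s)]))
  mean(w_all >= w_obs)
}

# exact hypergeometric upper-tail oracle: enumerate all draws of size k
enum_hyper_upper <- function(universe, set, k, min_overlap) {
  draws <- utils::combn(universe, k, simplify = FALSE)
  mean(vapply(draws, function(dr) length(intersect(dr, set)) >= min_overlap,
              logical(1)))
}

# small random bipartite edge list
random_bipartite <- function(n_mirnas, n_genes, p, seed) {
  set.seed(seed)
  m <- sprintf("hsa-mir-t%03d", seq_len(n_mirnas))
  g <- sprintf("G%04d", seq_len(n_genes))
  idx <- which(matrix(runif(n_mirnas * n_genes) < p, n_mirnas, n_genes),
               arr.ind = TRUE)
  data.frame(mirna = m[idx[, 1L]], gene = g[idx[, 2L]],
             stringsAsFactors = FALSE)
}

db_from_edges <- function(edges) {
  build_interaction_db(validated = list(
    data.frame(edges, source = "fixture", evidence = "validated",
               stringsAsFactors = FALSE)))
}
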
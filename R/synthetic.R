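# Synthetic input generators with planted ground truth. These emulate the
# study-style inputs (multi-source interaction tables, an 8-vs-8 miRNA
# expression matrix, a PPI edge list, GMT gene-set collections) so the full
# screening pipeline can be run and validated without any external data.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

default_mirna_ids <- function(n) sprintf("hsa-mir-s%04d", seq_len(n))
default_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a bipartite miRNA-target network as multi-source tables
#'
#' Builds a regulator-target network with controlled exclusivity and emits
#' it as validated-style and predicted-style source tables whose union
#' (validated pairs plus predicted pairs in >= 2 distinct sources) exactly
#' reconstructs the intended network. Each miRNA receives a Poisson
#' out-degree around `mean_targets`; a fraction `exclusive_fraction` of its
#' targets are private genes with no other regulator, and `hub_boost` adds
#' extra private genes to designated miRNAs (planted NOD hubs). Shared
#' genes are guaranteed at least two regulators, so the planted NOD of
#' every miRNA is exactly its private-gene count. Optional decoy pairs are
#' placed in exactly one predicted source and are therefore excluded by the
#' union rule.
#'
#' @param n_mirnas,n_genes dimensions of the regulator and gene namespaces.
#' @param mean_targets mean out-degree per miRNA.
#' @param exclusive_fraction fraction of each miRNA's targets that are
#'   exclusive, in [0, 1].
#' @param hub_boost named integer vector (names = miRNA ids) of extra
#'   exclusive targets for hub miRNAs.
#' @param n_validated_sources,n_predicted_sources number of source tables
#'   of each evidence class (>= 3 each by default).
#' @param validated_fraction probability an edge is carried by validated
#'   (rather than predicted-consensus) evidence.
#' @param n_decoy number of decoy pairs emitted with single-source
#'   predicted support only.
#' @param mirna_ids,gene_ids optional identifier vectors.
#' @param seed RNG seed.
#' @return list with `validated` and `predicted` (lists of record tables
#'   as from [read_interaction_table()]) and `truth`: `edges`,
#'   `planted_nod` (named integer), `gene_regulator_counts`, `n_edges`,
#'   `seed`.
#' @export
sim_interaction_network <- function(n_mirnas = 50, n_genes = 400,
                                    mean_targets = 8, exclusive_fraction = 0.3,
                                    hub_boost = integer(),
                                    n_validated_sources = 3,
                                    n_predicted_sources = 3,
                                    validated_fraction = 0.5,
                                    n_decoy = 0,
                                    mirna_ids = default_mirna_ids(n_mirnas),
                                    gene_ids = default_gene_ids(n_genes),
                                    seed = NULL) {
  stopifnot(exclusive_fraction >= 0, exclusive_fraction <= 1,
            n_validated_sources >= 1, n_predicted_sources >= 2)
  if (length(hub_boost) && is.null(names(hub_boost))) {
    stop("hub_boost must be named by miRNA id")
  }
  if (!all(names(hub_boost) %in% mirna_ids)) {
    stop("hub_boost names must be miRNA ids in the network")
  }
  with_seed(seed, {
    deg <- pmax(1L, stats::rpois(n_mirnas, mean_targets))
    names(deg) <- mirna_ids
    n_excl <- round(exclusive_fraction * deg)
    n_excl[names(hub_boost)] <- n_excl[names(hub_boost)] + hub_boost
    if (sum(n_excl) > n_genes) {
      stop("demanded exclusive genes (", sum(n_excl),
           ") exceed the gene namespace (", n_genes, ")")
    }
    n_shared_edges <- pmax(deg - n_excl, 0L)
    if (sum(n_shared_edges) > 0 && n_mirnas < 2L) {
      stop("shared targets need at least 2 miRNAs")
    }
    excl_pool <- sample(gene_ids, sum(n_excl))
    excl_assign <- split(excl_pool, rep(mirna_ids, n_excl))
    shared_pool <- setdiff(gene_ids, excl_pool)
    edges <- data.frame(mirna = character(), gene = character(),
                        stringsAsFactors = FALSE)
    for (m in mirna_ids) {
      g <- excl_assign[[m]]
      s <- n_shared_edges[[m]]
      if (s > 0 && length(shared_pool)) {
        g <- c(g, sample(shared_pool, min(s, length(shared_pool))))
      }
      if (length(g)) {
        edges <- rbind(edges, data.frame(mirna = m, gene = g,
                                         stringsAsFactors = FALSE))
      }
    }
    # any shared-pool gene left with a single regulator gets a second one,
    # so exclusivity is exactly the planted private-gene assignment
    reg_count <- table(edges$gene)
    lonely <- intersect(names(reg_count)[reg_count == 1L], shared_pool)
    for (g in lonely) {
      first <- edges$mirna[edges$gene == g][1L]
      second <- sample(setdiff(mirna_ids, first), 1L)
      edges <- rbind(edges, data.frame(mirna = second, gene = g,
                                       stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
    edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL

    val_names <- sprintf("validated_src%d", seq_len(n_validated_sources))
    prd_names <- sprintf("predicted_src%d", seq_len(n_predicted_sources))
    n_e <- nrow(edges)
    is_val <- stats::runif(n_e) < validated_fraction
    sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
    assign_rows <- function(idx, src_names, k_min) {
      out <- stats::setNames(vector("list", length(src_names)), src_names)
      for (i in idx) {
        k <- sample1(seq.int(k_min, length(src_names)))
        for (s in sample(src_names, k)) out[[s]] <- c(out[[s]], i)
      }
      out
    }
    val_rows <- assign_rows(which(is_val), val_names, 1L)
    prd_rows <- assign_rows(which(!is_val), prd_names, 2L)
    decoys <- NULL
    decoy_src <- character()
    if (n_decoy > 0) {
      dm <- sample(mirna_ids, n_decoy, replace = TRUE)
      dg <- sample(gene_ids, n_decoy, replace = TRUE)
      keep <- !paste(dm, dg) %in% paste(edges$mirna, edges$gene)
      decoys <- unique(data.frame(mirna = dm[keep], gene = dg[keep],
                                  stringsAsFactors = FALSE))
      # each decoy goes to exactly one predicted source
      decoy_src <- sample(prd_names, nrow(decoys), replace = TRUE)
    }
    mk_table <- function(rows, src, evid) {
      tab <- edges[rows, c("mirna", "gene"), drop = FALSE]
      if (evid == "predicted" && !is.null(decoys) && nrow(decoys)) {
        tab <- rbind(tab, decoys[decoy_src == src, , drop = FALSE])
      }
      tab <- unique(tab)
      tab$source <- src
      tab$evidence <- evid
      rownames(tab) <- NULL
      tab
    }
    validated <- lapply(val_names, function(s) mk_table(val_rows[[s]], s, "validated"))
    predicted <- lapply(prd_names, function(s) mk_table(prd_rows[[s]], s, "predicted"))
    planted_nod <- stats::setNames(as.integer(n_excl), mirna_ids)
    list(validated = validated, predicted = predicted,
         truth = list(edges = edges,
                      planted_nod = planted_nod,
                      gene_regulator_counts = as.integer(table(edges$gene)),
                      gene_ids = sort(unique(edges$gene)),
                      n_edges = nrow(edges),
                      seed = seed))
  })
}

#' Generate a case/control expression matrix with planted biomarkers
#'
#' Baseline per-miRNA intensities are log-normal (microarray-like positive
#' values) and per-cell noise is multiplicative log-normal, so linear fold
#' changes are well defined. For each planted biomarker row the case-group
#' mean is multiplied (direction `"up"`) or divided (`"down"`) by its
#' effect multiplier.
#'
#' @param n_mirnas number of rows (default 556).
#' @param n_case,n_control group sizes (default 8 each).
#' @param planted data.frame with columns `mirna`, `direction`
#'   (`"up"`/`"down"`), `effect` (multiplier > 0); NULL for a null matrix.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param noise_sd standard deviation of the log-scale multiplicative noise.
#' @param mirna_ids row identifiers.
#' @param seed RNG seed; a fixed seed gives a bit-identical matrix.
#' @return list with `eset` (an [expression_set()]) and `truth` (`planted`,
#'   `seed`).
#' @export
sim_expression <- function(n_mirnas = 556, n_case = 8, n_control = 8,
                           planted = NULL, baseline_meanlog = log(100),
                           baseline_sdlog = 1, noise_sd = 0.5,
                           mirna_ids = default_mirna_ids(n_mirnas),
                           seed = NULL) {
  if (!is.null(planted)) {
    if (anyDuplicated(planted$mirna)) stop("duplicate planted miRNA ids")
    if (!all(planted$mirna %in% mirna_ids)) {
      stop("planted ids must be expression row ids")
    }
    if (any(planted$effect <= 0)) stop("effect multipliers must be > 0")
    if (!all(planted$direction %in% c("up", "down"))) {
      stop("direction must be 'up' or 'down'")
    }
  }
  with_seed(seed, {
    n_s <- n_case + n_control
    base <- stats::rlnorm(n_mirnas, baseline_meanlog, baseline_sdlog)
    vals <- base * exp(matrix(stats::rnorm(n_mirnas * n_s, 0, noise_sd),
                              n_mirnas, n_s))
    rownames(vals) <- mirna_ids
    colnames(vals) <- c(sprintf("case_%02d", seq_len(n_case)),
                        sprintf("ctrl_%02d", seq_len(n_control)))
    group <- c(rep("case", n_case), rep("control", n_control))
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        f <- if (planted$direction[i] == "up") planted$effect[i] else 1 / planted$effect[i]
        vals[planted$mirna[i], group == "case"] <-
          vals[planted$mirna[i], group == "case"] * f
      }
    }
    list(eset = expression_set(vals, group),
         truth = list(planted = planted, seed = seed))
  })
}

#' Generate a synthetic protein-protein interaction graph
#'
#' Undirected simple graph over a gene namespace, either Erdos-Renyi
#' (`sample_gnm` with the edge count implied by `mean_degree`) or
#' scale-free (preferential attachment).
#'
#' @param genes character vector of node names (the interaction DB's gene
#'   namespace).
#' @param mean_degree target mean degree (< number of genes).
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param seed RNG seed.
#' @return list with `graph` (igraph), `truth` (`degree_sequence`,
#'   `n_edges`, `seed`).
#' @export
sim_ppi <- function(genes, mean_degree = 4, model = c("erdos_renyi", "scale_free"),
                    seed = NULL) {
  model <- match.arg(model)
  n <- length(genes)
  if (mean_degree >= n) stop("mean_degree must be < number of genes")
  with_seed(seed, {
    if (model == "erdos_renyi") {
      m <- round(mean_degree * n / 2)
      g <- igraph::sample_gnm(n, m, directed = FALSE)
    } else {
      g <- igraph::sample_pa(n, m = max(1L, round(mean_degree / 2)),
                             directed = FALSE)
    }
    igraph::V(g)$name <- genes
    list(graph = g,
         truth = list(degree_sequence = igraph::degree(g),
                      n_edges = igraph::ecount(g), seed = seed))
  })
}

#' Write a PPI graph as a two-column edge list TSV
#'
#' @param graph an igraph graph with named vertices.
#' @param path output path.
#' @export
write_ppi <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a GMT gene-set collection with one planted enriched set
#'
#' Random sets are drawn uniformly from the universe; one designated set
#' oversamples the given target genes with sampling weight `odds_ratio`
#' relative to the rest of the universe. At `odds_ratio = 1` the planted
#' set is indistinguishable from the others (null calibration).
#'
#' @param universe gene namespace.
#' @param n_sets number of sets.
#' @param set_size_range length-2 integer range of set sizes.
#' @param planted_genes genes the planted set oversamples.
#' @param odds_ratio sampling weight of planted genes in the planted set.
#' @param prefix set-id prefix.
#' @param seed RNG seed.
#' @return list with `collection` (a [gene_set_collection()]) and `truth`
#'   (`planted_set`, `odds_ratio`, `seed`).
#' @export
sim_gene_sets <- function(universe, n_sets = 20, set_size_range = c(10, 40),
                          planted_genes = character(), odds_ratio = 1,
                          prefix = "SET", seed = NULL) {
  stopifnot(length(set_size_range) == 2L, set_size_range[2L] <= length(universe))
  with_seed(seed, {
    sizes <- sample(seq.int(set_size_range[1L], set_size_range[2L]),
                    n_sets, replace = TRUE)
    ids <- sprintf("%s_%03d", prefix, seq_len(n_sets))
    w <- ifelse(universe %in% planted_genes, odds_ratio, 1)
    sets <- lapply(seq_len(n_sets), function(i) {
      if (i == 1L && length(planted_genes)) {
        sample(universe, sizes[i], prob = w)
      } else {
        sample(universe, sizes[i])
      }
    })
    names(sets) <- ids
    desc <- stats::setNames(
      c(if (length(planted_genes)) "planted synthetic set" else "synthetic set",
        rep("synthetic set", n_sets - 1L)), ids)
    list(collection = gene_set_collection(sets, descriptions = desc,
                                          universe = universe),
         truth = list(planted_set = if (length(planted_genes)) ids[1L] else NA_character_,
                      odds_ratio = odds_ratio, seed = seed))
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates and writes every pipeline input: per-source interaction TSVs,
#' an expression matrix and sample-label TSV, a PPI edge list, two GMT
#' collections (pathway-style and disease-style), a ground-truth JSON and a
#' ready-to-run `config.yaml`. The planted biomarkers are hub miRNAs in
#' the interaction network (large exclusive-target counts, all distinct so
#' the NOD ranking of the truth is unambiguous) that also carry strong
#' expression effects.
#'
#' @param dir output directory (created if needed).
#' @param seed single integer seed; per-artifact streams are derived from
#'   it and recorded in the truth file.
#' @param n_mirnas,n_genes interaction-network dimensions.
#' @param n_expr_mirnas number of expression rows (first rows of the miRNA
#'   namespace).
#' @param n_case,n_control sample sizes.
#' @param n_planted number of planted biomarker miRNAs.
#' @param effect expression effect multiplier for planted biomarkers.
#' @param noise_sd log-scale noise standard deviation.
#' @param mean_targets,exclusive_fraction network parameters.
#' @param ppi_mean_degree PPI mean degree.
#' @param n_sets,odds_ratio gene-set collection parameters.
#' @return invisibly, a list with the generated objects and the `truth`
#'   record (also written as `truth.json`).
#' @export
sim_bundle <- function(dir, seed = 1L, n_mirnas = 641, n_genes = 7706,
                       n_expr_mirnas = 556, n_case = 8, n_control = 8,
                       n_planted = 10, effect = 4, noise_sd = 0.5,
                       mean_targets = 51, exclusive_fraction = 0.1,
                       ppi_mean_degree = 6, n_sets = 50, odds_ratio = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mirna_ids <- default_mirna_ids(n_mirnas)
  planted_ids <- mirna_ids[seq_len(n_planted)]
  # distinct, well-separated planted NOD boosts for unambiguous rank order
  boosts <- stats::setNames(as.integer(round(seq(60, 15, length.out = n_planted))),
                            planted_ids)
  net <- sim_interaction_network(
    n_mirnas = n_mirnas, n_genes = n_genes, mean_targets = mean_targets,
    exclusive_fraction = exclusive_fraction, hub_boost = boosts,
    n_decoy = 200, mirna_ids = mirna_ids, seed = seed)
  dir.create(file.path(dir, "sources"), showWarnings = FALSE)
  src_paths <- list()
  for (tab in c(net$validated, net$predicted)) {
    src <- tab$source[1L]
    evid <- tab$evidence[1L]
    p <- file.path(dir, "sources", paste0(src, ".tsv"))
    utils::write.table(tab[, c("mirna", "gene")], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    src_paths[[src]] <- list(path = p, name = src, evidence = evid)
  }
  directions <- rep(c("up", "down"), length.out = n_planted)
  planted <- data.frame(mirna = planted_ids, direction = directions,
                        effect = effect, stringsAsFactors = FALSE)
  expr <- sim_expression(n_mirnas = n_expr_mirnas, n_case = n_case,
                         n_control = n_control, planted = planted,
                         noise_sd = noise_sd,
                         mirna_ids = mirna_ids[seq_len(n_expr_mirnas)],
                         seed = seed + 1L)
  write_expression(expr$eset, file.path(dir, "expression.tsv"),
                   file.path(dir, "labels.tsv"))
  genes_in_db <- net$truth$gene_ids
  ppi <- sim_ppi(genes_in_db, mean_degree = ppi_mean_degree, seed = seed + 2L)
  write_ppi(ppi$graph, file.path(dir, "ppi.tsv"))
  planted_excl <- unlist(lapply(planted_ids, function(m) {
    net$truth$edges$gene[net$truth$edges$mirna == m]
  }), use.names = FALSE)
  gmt_pathway <- sim_gene_sets(genes_in_db, n_sets = n_sets,
                               planted_genes = planted_excl,
                               odds_ratio = odds_ratio, prefix = "PATH",
                               seed = seed + 3L)
  gmt_disease <- sim_gene_sets(genes_in_db, n_sets = n_sets,
                               planted_genes = planted_excl,
                               odds_ratio = odds_ratio, prefix = "DIS",
                               seed = seed + 4L)
  write_gmt(gmt_pathway$collection, file.path(dir, "pathways.gmt"))
  write_gmt(gmt_disease$collection, file.path(dir, "disease.gmt"))
  truth <- list(
    seed = seed,
    planted_biomarkers = planted,
    planted_nod = as.list(net$truth$planted_nod[planted_ids]),
    n_network_edges = net$truth$n_edges,
    ppi_n_edges = ppi$truth$n_edges,
    planted_sets = c(gmt_pathway$truth$planted_set, gmt_disease$truth$planted_set)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(
    sources = unname(src_paths),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    collections = list(pathways = file.path(dir, "pathways.gmt"),
                       disease = file.path(dir, "disease.gmt")),
    alpha_de = 0.05, fc_threshold = 2, alpha_nod = 0.05,
    alpha_enrich = 0.05, auc_report_threshold = 0.90,
    min_predicted_support = 2, nod_reference = "db", seed = seed
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(list(network = net, expression = expr, ppi = ppi,
                 collections = list(pathways = gmt_pathway, disease = gmt_disease),
                 truth = truth, config_path = file.path(dir, "config.yaml")))
}
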
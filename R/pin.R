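# Protein-interaction subnetworks around each candidate miRNA's exclusive
# targets: N0 (targets present in the PPI), N1 (their direct neighbors),
# N2 = N0 + N1.

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV of undirected binary interactions. The graph is
#' symmetrized and deduplicated; self-loops are dropped (their count is
#' kept in the graph attribute `n_self_loops`). Lines starting with "#"
#' are skipped.
#'
#' @param path edge-list TSV path.
#' @param columns length-2 integer vector naming which columns hold the two
#'   interactors (default `c(1, 2)`; lets PSI-MITAB-style exports with extra
#'   columns be read by pointing at the identifier columns).
#' @return an undirected simple [igraph::igraph] graph over gene ids.
#' @export
read_ppi <- function(path, columns = c(1L, 2L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "n_self_loops", 0L)
    return(g)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < max(columns))
  if (length(bad)) stop("line ", bad[1L], " of '", path, "' is malformed")
  a <- normalize_gene_id(vapply(fields, `[[`, "", columns[1L]))
  b <- normalize_gene_id(vapply(fields, `[[`, "", columns[2L]))
  n_loops <- sum(a == b)
  keep <- a != b
  g <- igraph::graph_from_data_frame(data.frame(a[keep], b[keep]), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::set_graph_attr(g, "n_self_loops", n_loops)
}

#' Build one miRNA's protein-interaction subnetwork
#'
#' N0 = the miRNA's exclusive targets that are present in the PPI graph;
#' N1 = the PPI neighbors of N0, excluding N0 itself; N2 = |N0| + |N1|.
#' The edge table records the miRNA's regulatory edges to each N0 gene and
#' the PPI edges with at least one endpoint in N0 (pure one-hop star
#' expansion). `include_n1_edges = TRUE` additionally keeps PPI edges
#' between N1 genes.
#'
#' @param mirna_id the miRNA identifier.
#' @param targets character vector of the miRNA's exclusive target genes.
#' @param ppi PPI graph from [read_ppi()].
#' @param include_n1_edges also keep N1-N1 PPI edges (default FALSE).
#' @return object of class `pin`: list with `mirna_id`, `n0_genes`,
#'   `n1_genes`, `edges` (data.frame `from`, `to`, `type` in
#'   {"regulatory", "ppi"}), and `counts` (`nod`, `n0`, `n1`, `n2`).
#' @export
build_pin <- function(mirna_id, targets, ppi, include_n1_edges = FALSE) {
  targets <- unique(targets)
  nodes <- igraph::V(ppi)$name
  if (is.null(nodes)) nodes <- character()
  n0 <- sort(intersect(targets, nodes))
  if (length(n0)) {
    nb <- unique(unlist(lapply(n0, function(g) {
      igraph::neighbors(ppi, g)$name
    }), use.names = FALSE))
    n1 <- sort(setdiff(nb, n0))
  } else {
    n1 <- character()
  }
  reg <- if (length(n0)) {
    data.frame(from = mirna_id, to = n0, type = "regulatory",
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), type = character(),
               stringsAsFactors = FALSE)
  }
  ppi_edges <- reg[0, ]
  if (length(n0)) {
    el <- igraph::as_edgelist(ppi)
    touch0 <- el[, 1L] %in% n0 | el[, 2L] %in% n0
    keep <- touch0
    if (include_n1_edges) {
      within <- (el[, 1L] %in% c(n0, n1)) & (el[, 2L] %in% c(n0, n1))
      keep <- keep | within
    }
    if (any(keep)) {
      ppi_edges <- data.frame(from = el[keep, 1L], to = el[keep, 2L],
                              type = "ppi", stringsAsFactors = FALSE)
    }
  }
  structure(list(
    mirna_id = mirna_id,
    n0_genes = n0,
    n1_genes = n1,
    edges = rbind(reg, ppi_edges),
    counts = list(nod = length(targets), n0 = length(n0), n1 = length(n1),
                  n2 = length(n0) + length(n1))
  ), class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("PIN for %s: NOD=%d, N0=%d, N1=%d, N2=%d\n", x$mirna_id,
              x$counts$nod, x$counts$n0, x$counts$n1, x$counts$n2))
  invisible(x)
}

#' Export a PIN as node and edge tables
#'
#' Writes `<prefix>_nodes.tsv` (columns `node`, `role` in
#' {"mirna", "target", "neighbor"}) and `<prefix>_edges.tsv` (columns
#' `from`, `to`, `type` in {"regulatory", "ppi"}). The miRNA node is always
#' present, so an empty PIN exports one node and no edges.
#'
#' @param pin a `pin`.
#' @param prefix output path prefix.
#' @param format currently only `"tsv"`.
#' @return invisibly, the two file paths.
#' @export
write_pin <- function(pin, prefix, format = "tsv") {
  if (!identical(format, "tsv")) stop("unsupported format: ", format)
  nodes <- data.frame(
    node = c(pin$mirna_id, pin$n0_genes, pin$n1_genes),
    role = c("mirna", rep("target", length(pin$n0_genes)),
             rep("neighbor", length(pin$n1_genes))),
    stringsAsFactors = FALSE
  )
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pin$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = np, edges = ep))
}

#' Read a PIN exported by [write_pin()]
#'
#' @param prefix the path prefix used at export.
#' @return a `pin` (counts recomputed from the tables).
#' @export
read_pin <- function(prefix) {
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  n0 <- sort(nodes$node[nodes$role == "target"])
  n1 <- sort(nodes$node[nodes$role == "neighbor"])
  structure(list(
    mirna_id = nodes$node[nodes$role == "mirna"][1L],
    n0_genes = n0, n1_genes = n1, edges = edges,
    counts = list(nod = length(n0), n0 = length(n0), n1 = length(n1),
                  n2 = length(n0) + length(n1))
  ), class = "pin")
}

#' Build PINs for a set of candidate miRNAs and summarize
#'
#' @param exclusive_sets named list of exclusive-target gene vectors.
#' @param ppi PPI graph.
#' @param include_n1_edges passed to [build_pin()].
#' @return list with `pins` (named list of `pin`s) and `table`
#'   (data.frame `mirna`, `nod`, `n0`, `n1`, `n2`).
#' @export
pin_analysis <- function(exclusive_sets, ppi, include_n1_edges = FALSE) {
  pins <- lapply(names(exclusive_sets), function(m) {
    build_pin(m, exclusive_sets[[m]], ppi, include_n1_edges = include_n1_edges)
  })
  names(pins) <- names(exclusive_sets)
  tab <- data.frame(
    mirna = names(pins),
    nod = vapply(pins, function(p) p$counts$nod, integer(1)),
    n0 = vapply(pins, function(p) p$counts$n0, integer(1)),
    n1 = vapply(pins, function(p) p$counts$n1, integer(1)),
    n2 = vapply(pins, function(p) p$counts$n2, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(pins = pins, table = tab)
}
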
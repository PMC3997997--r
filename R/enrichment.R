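# Hypergeometric gene-set enrichment against GMT-backed collections.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene...`.
#' The universe defaults to the union of all member genes unless
#' overridden.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe; member genes outside it
#'   are dropped with a warning count.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of gene vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("line ", bad[1L], " of '", path, "' has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids),
                      universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of gene character vectors (each non-empty).
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional gene universe; defaults to the union of all set
#'   genes. Set members outside an explicit universe are dropped, with the
#'   number dropped recorded in attribute `"n_dropped"` and a warning.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets))) stop("sets must be a non-empty named list")
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  n_dropped <- 0L
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
  } else {
    trimmed <- lapply(sets, function(s) s[s %in% universe])
    n_dropped <- sum(lengths(sets)) - sum(lengths(trimmed))
    if (n_dropped > 0L) {
      warning(n_dropped, " set member(s) outside the universe dropped")
    }
    sets <- trimmed[lengths(trimmed) > 0L]
    if (!length(sets)) stop("no set overlaps the supplied universe")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe,
                 n_dropped = n_dropped),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric enrichment of a gene list
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the set, drawing
#' `|query ∩ universe|` genes without replacement from the universe. Query
#' genes absent from the universe are dropped from the draw (standard
#' practice) and counted in attribute `"n_query_dropped"`. Raw P values are
#' thresholded at `alpha`; a Benjamini-Hochberg column is always emitted.
#'
#' @param query character vector of gene ids.
#' @param collection a `gene_set_collection`.
#' @param alpha significance threshold on the raw P (default 0.05).
#' @return data.frame sorted by `p_value`: `set_id`, `description`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `p_bh`, `significant`, `overlap_genes` (semicolon-joined).
#' @export
hypergeom_enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  q <- intersect(query, collection$universe)
  n_dropped <- length(query) - length(q)
  if (!length(q)) warning("query has no overlap with the universe; all P = 1")
  N <- length(collection$universe)
  k <- length(q)
  res <- lapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    ov <- intersect(q, s)
    m <- length(s)
    # P(X >= |ov|), X ~ Hypergeom(N, m, k)
    p <- stats::phyper(length(ov) - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(set_id = id, description = collection$descriptions[[id]],
               overlap = length(ov), set_size = m, query_size = k,
               universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$set_id),
             c("set_id", "description", "overlap", "set_size", "query_size",
               "universe_size", "p_value", "p_bh", "significant",
               "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- n_dropped
  res
}

#' Enrich the candidates' exclusive target genes
#'
#' The query is the union of the candidates' exclusive-target sets (these
#' are disjoint across miRNAs, so the query size equals the sum of the
#' candidate NODs). One enrichment table is produced per collection.
#'
#' @param exclusive_sets named list of exclusive-target gene vectors, one
#'   per candidate miRNA (e.g. `exclusive_targets(compute_nod(db))`
#'   subset to the candidates).
#' @param collections named list of `gene_set_collection`s.
#' @param alpha raw-P significance threshold.
#' @return named list of enrichment data.frames; the query gene vector is
#'   attached as attribute `"query"`.
#' @export
enrich_candidates <- function(exclusive_sets, collections, alpha = 0.05) {
  if (!length(exclusive_sets)) stop("no candidate exclusive-target sets supplied")
  query <- unique(unlist(exclusive_sets, use.names = FALSE))
  out <- lapply(collections, hypergeom_enrich, query = query, alpha = alpha)
  attr(out, "query") <- query
  out
}
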
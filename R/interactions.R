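# miRNA-target interaction tables and the union interaction database.

#' Normalize a miRNA identifier
#'
#' miRNA names are lower-cased (the species prefix, e.g. "hsa-", is preserved
#' as part of the lower-cased name). Mature-arm and star variants such as
#' "miR-193b*" stay distinct identifiers. No alias resolution is attempted,
#' so joins across tables are purely lexical and deterministic.
#'
#' @param x character vector of miRNA names.
#' @return character vector of normalized names.
#' @export
normalize_mirna_id <- function(x) tolower(trimws(x))

#' Normalize a gene symbol
#'
#' Gene symbols are upper-cased and whitespace-trimmed.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_gene_id <- function(x) toupper(trimws(x))

#' Read a per-source miRNA-target table
#'
#' Reads a tab-separated table with at least two columns (miRNA, gene).
#' Lines starting with "#" are skipped. Identifiers are normalized
#' ([normalize_mirna_id()], [normalize_gene_id()]) and duplicate rows
#' collapsed, so the result has one record per distinct pair.
#'
#' @param path path to a UTF-8, tab-separated file.
#' @param source_name label recorded as the provenance of every record.
#' @param evidence either `"validated"` or `"predicted"`.
#' @param header logical; does the file carry a header line?
#' @return data.frame with columns `mirna`, `gene`, `source`, `evidence`.
#' @export
read_interaction_table <- function(path, source_name, evidence = c("validated", "predicted"),
                                   header = FALSE) {
  evidence <- match.arg(evidence)
  if (!file.exists(path)) stop("interaction table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (header && length(lines)) lines <- lines[-1L]
  lines_keep <- nzchar(trimws(lines))
  line_no <- which(lines_keep)
  lines <- lines[lines_keep]
  if (!length(lines)) {
    return(data.frame(mirna = character(), gene = character(),
                      source = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("line ", line_no[bad[1L]] + as.integer(header), " of '", path,
         "' has fewer than 2 tab-separated columns")
  }
  rec <- data.frame(
    mirna = normalize_mirna_id(vapply(fields, `[[`, "", 1L)),
    gene = normalize_gene_id(vapply(fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$mirna)) || any(!nzchar(rec$gene))) {
    stop("empty miRNA or gene identifier in '", path, "'")
  }
  rec <- unique(rec)
  rec$source <- source_name
  rec$evidence <- evidence
  rownames(rec) <- NULL
  rec
}

#' Build the union miRNA-mRNA interaction database
#'
#' Merges experimentally validated and computationally predicted
#' miRNA-target tables into a single deduplicated bipartite network. A
#' miRNA-gene pair enters the union if it occurs in at least one validated
#' source, or in at least `min_predicted_support` *distinct* predicted
#' sources. Validated evidence always suffices on its own; a pair seen in
#' one validated and one predicted source is included, with both recorded
#' in its provenance.
#'
#' @param validated list of record tables (as from [read_interaction_table()])
#'   with experimentally validated evidence.
#' @param predicted list of record tables with predicted evidence; each must
#'   carry a distinct source name.
#' @param min_predicted_support minimum number of distinct predicted sources
#'   required for a predicted-only pair (default 2).
#' @return an object of class `interaction_db`: a list with `edges` (a
#'   data.frame with columns `mirna`, `gene`, `n_validated_sources`,
#'   `n_predicted_sources`, `sources`), `mirna_index` (named list mapping
#'   each miRNA to its target genes) and `gene_index` (the exact transpose,
#'   mapping each gene to its regulator miRNAs).
#' @export
build_interaction_db <- function(validated = list(), predicted = list(),
                                 min_predicted_support = 2L) {
  if (!is.numeric(min_predicted_support) || min_predicted_support < 1) {
    stop("min_predicted_support must be >= 1")
  }
  empty <- data.frame(mirna = character(), gene = character(),
                      source = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  val <- if (length(validated)) do.call(rbind, validated) else empty
  prd <- if (length(predicted)) do.call(rbind, predicted) else empty
  if (nrow(prd)) {
    src_by_table <- lapply(predicted, function(x) unique(x$source))
    if (anyDuplicated(unlist(src_by_table))) {
      stop("each predicted table must carry a distinct source name")
    }
  }
  all_rec <- unique(rbind(val, prd))
  if (!nrow(all_rec)) {
    return(new_interaction_db(data.frame(
      mirna = character(), gene = character(),
      n_validated_sources = integer(), n_predicted_sources = integer(),
      sources = character(), stringsAsFactors = FALSE
    )))
  }
  key <- paste(all_rec$mirna, all_rec$gene, sep = "\r")
  is_val <- all_rec$evidence == "validated"
  n_val <- tapply(is_val, key, sum)
  n_prd <- tapply(!is_val, key, sum)
  src <- tapply(all_rec$source, key, function(s) paste(sort(unique(s)), collapse = ";"))
  keys <- names(n_val)
  keep <- n_val >= 1L | n_prd >= min_predicted_support
  keys <- keys[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    mirna = vapply(parts, `[[`, "", 1L),
    gene = vapply(parts, `[[`, "", 2L),
    n_validated_sources = as.integer(n_val[keys]),
    n_predicted_sources = as.integer(n_prd[keys]),
    sources = as.character(src[keys]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new_interaction_db(edges)
}

new_interaction_db <- function(edges) {
  structure(list(
    edges = edges,
    mirna_index = split(edges$gene, edges$mirna),
    gene_index = split(edges$mirna, edges$gene)
  ), class = "interaction_db")
}

#' Summarize an interaction database
#'
#' @param object an `interaction_db`.
#' @param ... ignored.
#' @return a list with `n_edges`, `n_mirnas`, `n_genes`.
#' @export
summary.interaction_db <- function(object, ...) {
  structure(list(
    n_edges = nrow(object$edges),
    n_mirnas = length(object$mirna_index),
    n_genes = length(object$gene_index)
  ), class = "summary.interaction_db")
}

#' @export
print.summary.interaction_db <- function(x, ...) {
  cat(sprintf("Union interaction database: %d pairs between %d miRNAs and %d genes\n",
              x$n_edges, x$n_mirnas, x$n_genes))
  invisible(x)
}

#' @export
print.interaction_db <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Write a union interaction database to TSV
#'
#' Columns: mirna, gene, n_validated_sources, n_predicted_sources, sources
#' (semicolon-joined). The file round-trips through [read_interaction_db()].
#'
#' @param db an `interaction_db`.
#' @param path output file path.
#' @export
write_interaction_db <- function(db, path) {
  utils::write.table(db$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a union interaction database written by [write_interaction_db()]
#'
#' @param path input file path.
#' @return an `interaction_db`.
#' @export
read_interaction_db <- function(path) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "integer", "integer", "character"),
                             stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new_interaction_db(edges)
}
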
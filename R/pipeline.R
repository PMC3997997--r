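# End-to-end biomarker screen: DE selection -> NOD ranking -> signed-rank
# significance filter -> ROC/AUC -> enrichment -> PIN expansion.

#' Screen for miRNA biomarkers by differential expression and NOD
#'
#' Runs the full network-based screen on in-memory objects. Stages:
#' (1) Student t-test and fold-change selection of differentially
#' expressed miRNAs; (2) NOD computation on the union interaction database
#' and ranking of the DE candidates by NOD, keeping those whose NOD is
#' significantly greater than the reference median (one-sided signed-rank
#' P < `alpha_nod`); (3) per-candidate ROC/AUC with confidence intervals,
#' orienting each by fold-change sign; (4, optional) hypergeometric
#' enrichment of the candidates' pooled exclusive targets against each
#' gene-set collection; (5, optional) one-hop PPI subnetwork expansion
#' (N0/N1/N2) per candidate.
#'
#' @param eset an [expression_set()].
#' @param db an `interaction_db` from [build_interaction_db()].
#' @param ppi optional PPI graph from [read_ppi()].
#' @param collections optional named list of [gene_set_collection()]s.
#' @param alpha_de DE P-value threshold (default 0.05).
#' @param fc_threshold minimum absolute linear fold change (default 2).
#' @param alpha_nod NOD significance threshold (default 0.05).
#' @param alpha_enrich enrichment significance threshold (default 0.05).
#' @param auc_report_threshold AUC threshold for the summary count
#'   (default 0.90).
#' @param nod_reference `"db"` or `"candidates"`; see
#'   [rank_candidates_by_nod()].
#' @param adjust multiple-testing mode for the DE stage (`"none"`/`"BH"`).
#' @param log_transform t-test on log2 intensities (default TRUE); see
#'   [de_candidates()].
#' @return object of class `nod_screen` with components `de`, `nod`,
#'   `ranking`, `report` (the retained-candidate table), `rocs`,
#'   `enrichment`, `pins`, `summary`, `params`.
#' @seealso [run_pipeline()] for the file-based interface.
#' @export
nod_screen <- function(eset, db, ppi = NULL, collections = NULL,
                       alpha_de = 0.05, fc_threshold = 2, alpha_nod = 0.05,
                       alpha_enrich = 0.05, auc_report_threshold = 0.90,
                       nod_reference = c("db", "candidates"),
                       adjust = c("none", "BH"), log_transform = TRUE) {
  nod_reference <- match.arg(nod_reference)
  adjust <- match.arg(adjust)
  stopifnot(inherits(eset, "expression_set"), inherits(db, "interaction_db"))
  de <- de_candidates(eset, alpha = alpha_de, fc_threshold = fc_threshold,
                      adjust = adjust, log_transform = log_transform)
  nod <- compute_nod(db)
  ranking <- rank_candidates_by_nod(de, nod, alpha_nod = alpha_nod,
                                    reference = nod_reference)
  report <- ranking[ranking$retained, , drop = FALSE]
  rownames(report) <- NULL
  roc <- NULL
  if (nrow(report)) {
    roc <- roc_analysis(eset, mirnas = report$mirna)
    report <- cbind(report,
                    roc$table[match(report$mirna, roc$table$mirna),
                              c("auc", "ci_low", "ci_high", "orientation")])
    rownames(report) <- NULL
  }
  excl <- exclusive_targets(nod)
  cand_excl <- excl[intersect(report$mirna, names(excl))]
  enr <- NULL
  if (!is.null(collections) && length(cand_excl)) {
    enr <- enrich_candidates(cand_excl, collections, alpha = alpha_enrich)
  }
  pins <- NULL
  if (!is.null(ppi) && length(cand_excl)) {
    pins <- pin_analysis(cand_excl, ppi)
  }
  summ <- list(
    n_mirnas_tested = nrow(de),
    n_de_candidates = sum(de$candidate),
    n_retained = nrow(report),
    total_exclusive_genes = sum(lengths(cand_excl)),
    auc = if (nrow(report)) summarize_auc(report$auc, auc_report_threshold) else NULL
  )
  structure(list(
    de = de, nod = nod, ranking = ranking, report = report,
    rocs = if (!is.null(roc)) roc$rocs else NULL,
    enrichment = enr, pins = pins, summary = summ,
    params = list(alpha_de = alpha_de, fc_threshold = fc_threshold,
                  alpha_nod = alpha_nod, alpha_enrich = alpha_enrich,
                  auc_report_threshold = auc_report_threshold,
                  nod_reference = nod_reference, adjust = adjust,
                  log_transform = log_transform)
  ), class = "nod_screen")
}

#' @export
print.nod_screen <- function(x, ...) {
  cat("miRNA biomarker screen (NOD-based)\n")
  cat(sprintf("  %d miRNAs tested, %d differentially expressed (P<%g, |FC|>=%g)\n",
              x$summary$n_mirnas_tested, x$summary$n_de_candidates,
              x$params$alpha_de, x$params$fc_threshold))
  cat(sprintf("  %d retained after NOD significance (P<%g, reference: %s)\n",
              x$summary$n_retained, x$params$alpha_nod, x$params$nod_reference))
  if (nrow(x$report)) {
    cols <- intersect(c("mirna", "nod", "nod_p", "p_value", "fc_linear", "auc"),
                      names(x$report))
    print(x$report[, cols], digits = 3)
  }
  invisible(x)
}

#' @export
summary.nod_screen <- function(object, ...) {
  s <- object$summary
  if (!is.null(s$auc)) {
    cat(sprintf("AUC: min %.2f, max %.2f, mean %.2f; %d of %d at or above %.2f\n",
                s$auc$min, s$auc$max, s$auc$mean, s$auc$n_at_or_above,
                s$n_retained, s$auc$threshold))
  }
  cat(sprintf("Total exclusive target genes across retained candidates: %d\n",
              s$total_exclusive_genes))
  invisible(s)
}

#' Plot method for a biomarker screen
#'
#' `which = "roc"` draws one ROC panel per retained candidate;
#' `which = "nod"` draws the boxplot comparison of the retained
#' candidates' NOD values against the full database population.
#'
#' @param x a `nod_screen`.
#' @param which `"roc"` or `"nod"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.nod_screen <- function(x, which = c("roc", "nod"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    if (is.null(x$rocs) || !length(x$rocs)) stop("no ROC results to plot")
    n <- length(x$rocs)
    nc <- ceiling(sqrt(n))
    op <- graphics::par(mfrow = c(ceiling(n / nc), nc), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (r in x$rocs) {
      graphics::plot(r$curve$fpr, r$curve$tpr, type = "l",
                     xlab = "1 - specificity", ylab = "sensitivity",
                     main = sprintf("%s (AUC %.2f)", r$mirna_id, r$auc), ...)
      graphics::abline(0, 1, lty = 2, col = "grey")
    }
  } else {
    pop <- x$nod$nod
    grp <- x$report$nod
    if (!length(grp)) stop("no retained candidates to plot")
    graphics::boxplot(list(candidates = grp, `all miRNAs` = pop),
                      ylab = "NOD", ...)
  }
  invisible(x)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills in
#' defaults and collects *all* problems rather than stopping at the first.
#' Required keys: `sources` (list of `{path, name, evidence}`),
#' `expression`, `labels`. Optional: `ppi`, `collections` (named paths),
#' `alpha_de` (default 0.05), `fc_threshold` (2), `alpha_nod` (0.05),
#' `alpha_enrich` (0.05), `auc_report_threshold` (0.90),
#' `min_predicted_support` (2), `nod_reference` ("db"), `adjust` ("none"),
#' `log_transform` (TRUE), `seed`. Unknown keys give warnings.
#'
#' @param config path to a YAML file, or a list.
#' @return a validated config list of class `pipeline_config`; on failure,
#'   an error naming every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  defaults <- list(alpha_de = 0.05, fc_threshold = 2, alpha_nod = 0.05,
                   alpha_enrich = 0.05, auc_report_threshold = 0.90,
                   min_predicted_support = 2, nod_reference = "db",
                   adjust = "none", log_transform = TRUE, seed = NULL,
                   ppi = NULL, collections = NULL)
  known <- c(names(defaults), "sources", "expression", "labels")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    warning("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  errs <- character()
  for (k in c("sources", "expression", "labels")) {
    if (is.null(config[[k]])) errs <- c(errs, paste0("missing required key: ", k))
  }
  if (!is.null(config$sources)) {
    for (i in seq_along(config$sources)) {
      s <- config$sources[[i]]
      if (!all(c("path", "name", "evidence") %in% names(s))) {
        errs <- c(errs, sprintf("sources[%d] needs path, name, evidence", i))
      } else {
        if (!file.exists(s$path)) errs <- c(errs, paste0("missing file: ", s$path))
        if (!s$evidence %in% c("validated", "predicted")) {
          errs <- c(errs, sprintf("sources[%d] evidence must be validated/predicted", i))
        }
      }
    }
  }
  for (k in c("expression", "labels", "ppi")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      errs <- c(errs, paste0("missing file: ", config[[k]]))
    }
  }
  if (!is.null(config$collections)) {
    for (p in unlist(config$collections)) {
      if (!file.exists(p)) errs <- c(errs, paste0("missing file: ", p))
    }
  }
  for (k in c("alpha_de", "alpha_nod", "alpha_enrich")) {
    v <- config[[k]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      errs <- c(errs, sprintf("%s must be in [0, 1], got %s", k, format(v)))
    }
  }
  if (!is.numeric(config$fc_threshold) || config$fc_threshold < 0) {
    errs <- c(errs, "fc_threshold must be >= 0")
  }
  if (!is.numeric(config$min_predicted_support) || config$min_predicted_support < 1) {
    errs <- c(errs, "min_predicted_support must be >= 1")
  }
  if (!config$nod_reference %in% c("db", "candidates")) {
    errs <- c(errs, "nod_reference must be 'db' or 'candidates'")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the full pipeline from a configuration
#'
#' File-based front end to [nod_screen()]: loads every input named in the
#' config, runs the screen, and writes each stage's table as plain TSV into
#' `out_dir` together with a JSON manifest (row counts per stage, the
#' thresholds applied, and the seed). Identical config and inputs give
#' byte-identical tables. If a stage fails, the error names the stage and
#' a `FAILED` marker file records it; previously written outputs are kept.
#'
#' @param config a `pipeline_config` from [validate_config()], or a path.
#' @param out_dir output directory for stage tables (default
#'   `"mirnod_run"`).
#' @param verbose log one line per stage (default TRUE).
#' @return the `nod_screen` object, invisibly; side effect: TSV and JSON
#'   artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = "mirnod_run", verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log1 <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  on.exit({
    writeLines(paste("failed at stage:", stage), file.path(out_dir, "FAILED"))
  })
  run_stage <- function(name, fun) {
    stage <<- name
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  db <- run_stage("interactions", function() {
    tabs <- lapply(config$sources, function(s) {
      read_interaction_table(s$path, s$name, s$evidence)
    })
    evid <- vapply(config$sources, `[[`, "", "evidence")
    build_interaction_db(validated = tabs[evid == "validated"],
                         predicted = tabs[evid == "predicted"],
                         min_predicted_support = config$min_predicted_support)
  })
  s <- summary(db)
  log1("interactions: %d pairs, %d miRNAs, %d genes", s$n_edges, s$n_mirnas, s$n_genes)
  eset <- run_stage("expression", function() {
    read_expression(config$expression, config$labels)
  })
  log1("expression: %d miRNAs x %d samples", nrow(eset$values), ncol(eset$values))
  ppi <- NULL
  if (!is.null(config$ppi)) {
    ppi <- run_stage("ppi", function() read_ppi(config$ppi))
    log1("ppi: %d nodes, %d edges", igraph::vcount(ppi), igraph::ecount(ppi))
  }
  collections <- NULL
  if (!is.null(config$collections)) {
    collections <- run_stage("collections", function() {
      lapply(config$collections, read_gmt)
    })
    log1("collections: %s", paste(names(collections), collapse = ", "))
  }
  screen <- run_stage("screen", function() {
    nod_screen(eset, db, ppi = ppi, collections = collections,
               alpha_de = config$alpha_de, fc_threshold = config$fc_threshold,
               alpha_nod = config$alpha_nod, alpha_enrich = config$alpha_enrich,
               auc_report_threshold = config$auc_report_threshold,
               nod_reference = config$nod_reference, adjust = config$adjust,
               log_transform = config$log_transform)
  })
  log1("screen: %d DE candidates, %d retained", screen$summary$n_de_candidates,
       screen$summary$n_retained)
  run_stage("write", function() {
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_interaction_db(db, file.path(out_dir, "union_db.tsv"))
    wt(screen$de, "de_table.tsv")
    nod_tab <- screen$nod
    nod_tab$exclusive_targets <- vapply(
      exclusive_targets(screen$nod)[nod_tab$mirna],
      function(g) paste(sort(g), collapse = ";"), character(1))
    wt(nod_tab, "nod_table.tsv")
    wt(screen$ranking, "candidate_ranking.tsv")
    wt(screen$report, "report.tsv")
    if (!is.null(screen$enrichment)) {
      for (nm in names(screen$enrichment)) {
        wt(screen$enrichment[[nm]], paste0("enrichment_", nm, ".tsv"))
      }
    }
    if (!is.null(screen$pins)) {
      wt(screen$pins$table, "pin_summary.tsv")
      for (nm in names(screen$pins$pins)) {
        write_pin(screen$pins$pins[[nm]],
                  file.path(out_dir, paste0("pin_", gsub("[^A-Za-z0-9._-]", "_", nm))))
      }
    }
    manifest <- list(
      params = config[c("alpha_de", "fc_threshold", "alpha_nod", "alpha_enrich",
                        "auc_report_threshold", "min_predicted_support",
                        "nod_reference", "adjust", "log_transform")],
      seed = config$seed,
      db = unclass(s),
      stages = list(n_mirnas_tested = screen$summary$n_mirnas_tested,
                    n_de_candidates = screen$summary$n_de_candidates,
                    n_retained = screen$summary$n_retained,
                    total_exclusive_genes = screen$summary$total_exclusive_genes)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  on.exit()
  invisible(screen)
}
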
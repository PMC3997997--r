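# Case/control expression matrix handling and differential-expression selection.

#' Construct an expression set
#'
#' @param values numeric matrix, rows = miRNAs (unique rownames), columns =
#'   samples; normalized linear-scale intensities.
#' @param group character or factor of length `ncol(values)` with values
#'   `"case"` / `"control"`.
#' @return an object of class `expression_set`.
#' @export
expression_set <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    if (length(dup)) stop("duplicate miRNA row id(s): ", paste(dup, collapse = ", "))
    stop("expression matrix must have unique rownames (miRNA ids)")
  }
  group <- as.character(group)
  if (length(group) != ncol(values)) stop("one group label per sample required")
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  if (sum(group == "case") < 2L || sum(group == "control") < 2L) {
    stop("need at least 2 samples per group")
  }
  structure(list(values = values, group = factor(group, levels = c("control", "case"))),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("Expression set: %d miRNAs x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' Read an expression matrix with sample labels
#'
#' The expression file is TSV with a header of sample ids and one row per
#' miRNA (first column = miRNA id). `labels` maps each sample id to
#' `"case"` or `"control"`; every column of the matrix must be labelled.
#' Rows containing any non-numeric cell are rejected, naming the row id.
#'
#' @param path expression TSV path.
#' @param labels named character vector (names = sample ids), or a two-column
#'   data.frame `(sample, group)`, or the path of such a TSV.
#' @return an `expression_set`.
#' @export
read_expression <- function(path, labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- utils::read.table(labels, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2L]]), labels[[1L]])
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  unknown <- setdiff(samples, names(labels))
  if (length(unknown)) {
    stop("sample id(s) missing from label map: ", paste(unknown, collapse = ", "))
  }
  num <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  bad <- ids[apply(is.na(num), 1L, any)]
  if (length(bad)) stop("non-numeric value(s) in row(s): ", paste(bad, collapse = ", "))
  rownames(num) <- ids
  colnames(num) <- samples
  expression_set(num, labels[samples])
}

#' Write an expression set (and its labels) to TSV
#'
#' @param eset an `expression_set`.
#' @param path expression TSV path.
#' @param labels_path optional path for a `(sample, group)` labels TSV.
#' @export
write_expression <- function(eset, path, labels_path = NULL) {
  df <- data.frame(mirna = rownames(eset$values), eset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample = colnames(eset$values), group = as.character(eset$group)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Classic equal-variance two-sided t-test. Degenerate inputs follow a
#' documented convention: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means gives
#' `t = +/-Inf, p = 0`.
#'
#' @param case_values,control_values numeric vectors, length >= 2 each.
#' @return list with `t_stat`, `p_value`, `df`.
#' @export
student_t <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  if (!all(is.finite(case_values)) || !all(is.finite(control_values))) {
    stop("values must be finite")
  }
  m1 <- mean(case_values); m2 <- mean(control_values)
  sp2 <- ((n1 - 1) * stats::var(case_values) + (n2 - 1) * stats::var(control_values)) /
    (n1 + n2 - 2)
  df <- n1 + n2 - 2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) return(list(t_stat = 0, p_value = 1, df = df))
    return(list(t_stat = sign(m1 - m2) * Inf, p_value = 0, df = df))
  }
  t <- (m1 - m2) / se
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

#' Fold change between group means
#'
#' Computed on linear-scale group means. Down-regulation uses the signed
#' convention: when the case mean is below the control mean the linear fold
#' change is reported as `-(control/case)`, so a halving appears as -2 and
#' the magnitude filter is `abs(fc_linear) >= threshold`. The log2 fold
#' change is `log2(case/control)` when both means are positive, `NA`
#' otherwise.
#'
#' @param case_values,control_values numeric vectors.
#' @return list with `fc_linear`, `fc_log2`.
#' @export
fold_change <- function(case_values, control_values) {
  m1 <- mean(case_values); m2 <- mean(control_values)
  fc_log2 <- if (m1 > 0 && m2 > 0) log2(m1 / m2) else NA_real_
  if (m1 == m2) {
    fc_linear <- 1
  } else if (m1 > 0 && m2 > 0) {
    fc_linear <- if (m1 >= m2) m1 / m2 else -(m2 / m1)
  } else {
    fc_linear <- NA_real_
  }
  list(fc_linear = fc_linear, fc_log2 = fc_log2)
}

# Vectorized pooled-variance t over matrix rows; same conventions as student_t.
row_t_stats <- function(values, group) {
  case <- values[, group == "case", drop = FALSE]
  ctrl <- values[, group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1L, stats::var); v2 <- apply(ctrl, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  }
  list(t = t, p = p, m1 = m1, m2 = m2, df = df, zero_variance = zero)
}

#' Select differentially expressed candidate miRNAs
#'
#' One row per miRNA with the Student t statistic, raw two-sided P value,
#' linear and log2 fold change, and a candidate flag. A miRNA is a
#' candidate iff `p < alpha` and `abs(fc_linear) >= fc_threshold`. No
#' multiple-testing correction is applied by default (the screening design
#' uses raw P at 0.05); a Benjamini-Hochberg adjusted column is always
#' emitted, and `adjust = "BH"` makes the candidate flag use it instead.
#' Rows with zero variance in both groups are reported (flagged in the
#' `zero_variance` column), never silently dropped.
#'
#' @param eset an `expression_set`.
#' @param alpha P value threshold (default 0.05).
#' @param fc_threshold minimum absolute linear fold change (default 2).
#' @param adjust `"none"` (raw P, default) or `"BH"`.
#' @param log_transform run the t-test on log2-transformed intensities
#'   (default TRUE; the standard variance-stabilizing scale for microarray
#'   intensities, under which the test is well calibrated). Fold changes
#'   are always computed on linear-scale group means. Requires strictly
#'   positive values; set FALSE for data already on a log or signed scale.
#' @return data.frame with columns `mirna`, `t_stat`, `p_value`, `p_bh`,
#'   `fc_linear`, `fc_log2`, `zero_variance`, `candidate`, sorted by
#'   `p_value`.
#' @export
de_candidates <- function(eset, alpha = 0.05, fc_threshold = 2,
                          adjust = c("none", "BH"), log_transform = TRUE) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(eset, "expression_set"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (fc_threshold < 0) stop("fc_threshold must be >= 0")
  test_values <- eset$values
  if (log_transform) {
    if (any(test_values <= 0)) {
      stop("log_transform = TRUE needs strictly positive intensities; ",
           "set log_transform = FALSE for data already on a log scale")
    }
    test_values <- log2(test_values)
  }
  st <- row_t_stats(test_values, eset$group)
  # fold change always on linear-scale group means
  st$m1 <- rowMeans(eset$values[, eset$group == "case", drop = FALSE])
  st$m2 <- rowMeans(eset$values[, eset$group == "control", drop = FALSE])
  both_pos <- st$m1 > 0 & st$m2 > 0
  fc_lin <- ifelse(st$m1 == st$m2, 1,
                   ifelse(both_pos,
                          ifelse(st$m1 >= st$m2, st$m1 / st$m2, -(st$m2 / st$m1)),
                          NA_real_))
  fc_l2 <- ifelse(both_pos, log2(st$m1 / st$m2), NA_real_)
  p_bh <- stats::p.adjust(st$p, method = "BH")
  p_used <- if (adjust == "BH") p_bh else st$p
  res <- data.frame(
    mirna = rownames(eset$values),
    t_stat = st$t,
    p_value = st$p,
    p_bh = p_bh,
    fc_linear = fc_lin,
    fc_log2 = fc_l2,
    zero_variance = st$zero_variance,
    candidate = p_used < alpha & !is.na(fc_lin) & abs(fc_lin) >= fc_threshold,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_value, res$mirna), , drop = FALSE]
  rownames(res) <- NULL
  res
}
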
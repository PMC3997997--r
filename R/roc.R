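# ROC curves and AUC for single-miRNA case/control discrimination.

#' ROC curve and AUC for one score vector
#'
#' AUC is computed by the Mann-Whitney identity: the probability that a
#' randomly chosen case scores above a randomly chosen control, with tied
#' pairs counted 1/2. The curve is traced over all score thresholds. With
#' `orientation = "flipped"` the scores are negated before analysis: the
#' screening pipeline flips down-regulated miRNAs (by fold-change sign) so
#' that AUC always measures discriminatory accuracy, not direction.
#'
#' @param scores numeric vector of per-sample scores (e.g. one miRNA's
#'   expression values).
#' @param labels character/factor vector of `"case"` / `"control"`, same
#'   length as `scores`; both classes must be present.
#' @param orientation `"as_is"` (default) or `"flipped"` (negate scores).
#' @param mirna_id optional identifier carried into the result.
#' @return object of class `roc_result`: list with `mirna_id`, `auc`,
#'   `curve` (data.frame `fpr`, `tpr` from (0,0) to (1,1)), `orientation`,
#'   `n_case`, `n_control`, and the (oriented) `scores`/`labels` used.
#' @export
compute_auc <- function(scores, labels, orientation = c("as_is", "flipped"),
                        mirna_id = NA_character_) {
  orientation <- match.arg(orientation)
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c("case", "control"))) stop("labels must be 'case'/'control'")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!any(labels == "case") || !any(labels == "control")) {
    stop("both classes must be present")
  }
  if (orientation == "flipped") scores <- -scores
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  r <- rank(scores)
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # curve: sweep thresholds from +Inf down through each distinct score
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) sum(scores[is_case] >= t) / n1, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores[!is_case] >= t) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  structure(list(mirna_id = mirna_id, auc = auc, curve = curve,
                 orientation = orientation, n_case = n1, n_control = n0,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC = %.4f (%d case vs %d control, orientation %s)\n",
              if (is.na(x$mirna_id)) "" else paste0(" [", x$mirna_id, "]"),
              x$auc, x$n_case, x$n_control, x$orientation))
  invisible(x)
}

# trapezoidal area under the (fpr, tpr) polyline
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Confidence interval for an AUC
#'
#' Default method is the Hanley-McNeil standard error
#' \eqn{SE^2 = [A(1-A) + (n_1-1)(Q_1-A^2) + (n_0-1)(Q_2-A^2)]/(n_1 n_0)}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}; the interval is
#' truncated to [0, 1]. `method = "delong"` uses the DeLong placement
#' variance instead (requires the `roc_result` to carry scores).
#'
#' @param roc a `roc_result`, or a bare AUC value (then `n_case` and
#'   `n_control` are required and only `"hanley"` is available).
#' @param level confidence level in (0, 1), default 0.95.
#' @param method `"hanley"` (default) or `"delong"`.
#' @param n_case,n_control group sizes, taken from `roc` when omitted.
#' @return list with `ci_low`, `ci_high`, `se`, `method`.
#' @export
auc_ci <- function(roc, level = 0.95, method = c("hanley", "delong"),
                   n_case = NULL, n_control = NULL) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (inherits(roc, "roc_result")) {
    a <- roc$auc
    if (is.null(n_case)) n_case <- roc$n_case
    if (is.null(n_control)) n_control <- roc$n_control
  } else {
    a <- as.numeric(roc)
    if (is.null(n_case) || is.null(n_control)) {
      stop("n_case and n_control are required when roc is a bare AUC")
    }
    if (method == "delong") stop("DeLong needs a roc_result with scores")
  }
  if (n_case < 2L || n_control < 2L) stop("group sizes must be >= 2")
  if (method == "hanley") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n_case - 1) * (q1 - a^2) +
                  (n_control - 1) * (q2 - a^2)) / (n_case * n_control))
  } else {
    x <- roc$scores[roc$labels == "case"]
    y <- roc$scores[roc$labels == "control"]
    # per-observation placements
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
    se <- sqrt(stats::var(v10) / n_case + stats::var(v01) / n_control)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ci_low = max(0, a - z * se), ci_high = min(1, a + z * se),
       se = se, method = method)
}

#' Summarize a set of AUCs
#'
#' @param aucs numeric vector of AUC values, or a list of `roc_result`s.
#' @param threshold AUC threshold for the count (default 0.90, inclusive).
#' @return list with `min`, `max`, `mean`, `n_at_or_above`, `threshold`.
#' @export
summarize_auc <- function(aucs, threshold = 0.90) {
  if (is.list(aucs)) aucs <- vapply(aucs, function(r) r$auc, numeric(1))
  if (!length(aucs)) stop("no AUC values supplied")
  list(min = min(aucs), max = max(aucs), mean = mean(aucs),
       n_at_or_above = sum(aucs >= threshold), threshold = threshold)
}

#' Per-miRNA ROC analysis of an expression set
#'
#' Runs [compute_auc()] on each requested miRNA row, orienting each by the
#' sign of its fold change (down-regulated miRNAs are flipped), and attaches
#' Hanley-McNeil confidence intervals.
#'
#' @param eset an `expression_set`.
#' @param mirnas miRNA ids (rows) to analyse; default all rows.
#' @param level confidence level for the CI.
#' @param ci_method `"hanley"` or `"delong"`.
#' @return list with `table` (data.frame `mirna`, `auc`, `ci_low`,
#'   `ci_high`, `orientation`) and `rocs` (named list of `roc_result`s).
#' @export
roc_analysis <- function(eset, mirnas = rownames(eset$values), level = 0.95,
                         ci_method = c("hanley", "delong")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(eset, "expression_set"))
  missing_ids <- setdiff(mirnas, rownames(eset$values))
  if (length(missing_ids)) {
    stop("miRNA(s) not in expression set: ", paste(missing_ids, collapse = ", "))
  }
  labels <- as.character(eset$group)
  rocs <- lapply(mirnas, function(m) {
    v <- eset$values[m, ]
    fc <- fold_change(v[labels == "case"], v[labels == "control"])
    ori <- if (!is.na(fc$fc_linear) && fc$fc_linear < 0) "flipped" else "as_is"
    compute_auc(v, labels, orientation = ori, mirna_id = m)
  })
  names(rocs) <- mirnas
  cis <- lapply(rocs, auc_ci, level = level, method = ci_method)
  tab <- data.frame(
    mirna = mirnas,
    auc = vapply(rocs, function(r) r$auc, numeric(1)),
    ci_low = vapply(cis, function(ci) ci$ci_low, numeric(1)),
    ci_high = vapply(cis, function(ci) ci$ci_high, numeric(1)),
    orientation = vapply(rocs, function(r) r$orientation, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(table = tab, rocs = rocs)
}
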
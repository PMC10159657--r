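#' Confusion counts at a probability threshold
#'
#' Counts follow the same `>=` convention as [classify()]: a pair is called
#' binding iff its probability reaches the threshold.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param truth 0/1 vector of the same length.
#' @param threshold Classification threshold; default 0.5.
#' @return Named integer vector `c(tp, fp, tn, fn)`; the four counts sum to
#'   the number of evaluated pairs.
#' @export
confusion_at_threshold <- function(probabilities, truth, threshold = 0.5) {
  if (length(probabilities) != length(truth))
    stop("probabilities and truth must have equal length")
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth must be binary 0/1")
  pred <- classify(probabilities, threshold)
  c(tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L))
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random binding pair is
#' scored above a random non-binding pair, with ties counted half. It is
#' computed from midranks, which is exactly equivalent to integrating the
#' ROC curve with trapezoids, and is invariant under strictly monotone
#' transforms of the scores.
#'
#' @param probabilities Numeric score vector (need not be calibrated).
#' @param truth 0/1 vector; both classes must be present.
#' @return Object of class `"tcrbind_roc"`: list with `auc` and `curve`,
#'   a data frame of `(threshold, fpr, tpr)` points, one per distinct score
#'   plus the two endpoints.
#' @export
roc_auc <- function(probabilities, truth) {
  truth <- as.integer(truth)
  if (length(probabilities) != length(truth))
    stop("probabilities and truth must have equal length")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an ROC curve")
  r <- rank(probabilities, ties.method = "average")
  auc <- (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # Curve: sweep thresholds downward over the distinct scores.
  ord <- order(probabilities, decreasing = TRUE)
  p_s <- probabilities[ord]; t_s <- truth[ord]
  last <- !duplicated(p_s, fromLast = TRUE)  # last row of each tie group
  tpr <- cumsum(t_s == 1L)[last] / n_pos
  fpr <- cumsum(t_s == 0L)[last] / n_neg
  curve <- data.frame(threshold = c(Inf, p_s[last]),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "tcrbind_roc")
}

#' @export
print.tcrbind_roc <- function(x, ...) {
  cat("ROC over", x$n_pos, "binding /", x$n_neg, "non-binding pairs; AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' @method plot tcrbind_roc
#' @export
plot.tcrbind_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' The four benchmark metrics at a threshold
#'
#' Reports AUC, accuracy, sensitivity and specificity:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' accuracy = (tp+tn)/n, all at the stated threshold. If only one class is
#' present in `truth`, the threshold metrics are still reported but the AUC
#' is `NA` (unavailable, not zero).
#'
#' @param probabilities,truth,threshold As in [confusion_at_threshold()].
#' @param stratum Optional stratum label recorded in the report row.
#' @return One-row data frame: `stratum`, `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @examples
#' # operating point with 94 tp / 6 fn / 90 tn / 10 fp:
#' p <- c(rep(.9, 94), rep(.1, 6), rep(.1, 90), rep(.9, 10))
#' y <- c(rep(1, 100), rep(0, 100))
#' metrics_report(p, y)[, c("sensitivity", "specificity")]  # 0.94, 0.90
#' @export
metrics_report <- function(probabilities, truth, threshold = 0.5,
                           stratum = NA_character_) {
  if (!length(probabilities)) stop("empty input")
  truth <- as.integer(truth)
  cm <- confusion_at_threshold(probabilities, truth, threshold)
  n_pos <- cm[["tp"]] + cm[["fn"]]; n_neg <- cm[["tn"]] + cm[["fp"]]
  auc <- if (n_pos > 0L && n_neg > 0L) roc_auc(probabilities, truth)$auc
         else NA_real_
  data.frame(stratum = stratum,
             auc = auc,
             accuracy = (cm[["tp"]] + cm[["tn"]]) / sum(cm),
             sensitivity = if (n_pos > 0) cm[["tp"]] / n_pos else NA_real_,
             specificity = if (n_neg > 0) cm[["tn"]] / n_neg else NA_real_,
             threshold = threshold, n_pos = n_pos, n_neg = n_neg,
             stringsAsFactors = FALSE)
}

#' Per-stratum evaluation report
#'
#' One [metrics_report()] row per stratum (e.g. pathogen source, cancer
#' type, dominant vs other peptides). Strata containing a single class get
#' threshold metrics with AUC marked unavailable (`NA`). Per-stratum
#' confusion counts sum to the pooled counts by construction.
#'
#' @param strata Vector of stratum labels, one per evaluated pair.
#' @param probabilities,truth,threshold As in [metrics_report()].
#' @return Data frame with one row per stratum, in first-appearance order.
#' @export
stratified_report <- function(strata, probabilities, truth, threshold = 0.5) {
  stopifnot(length(strata) == length(probabilities),
            length(probabilities) == length(truth))
  levels <- unique(strata)
  out <- do.call(rbind, lapply(levels, function(s) {
    rows <- strata == s
    metrics_report(probabilities[rows], truth[rows], threshold, stratum = s)
  }))
  rownames(out) <- NULL
  out
}
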
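# Internal: drop incomplete observations and check both classes present.
roc_prepare <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_invalid("scores and labels must have equal length")
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels)) {
    abort_insufficient("ROC needs both diseased and non-diseased cases")
  }
  list(scores = scores, labels = labels)
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC over the unique observed score values with the
#' inclusive `score >= threshold` positivity rule (scores oriented so
#' larger means more diseased).  The AUC equals the Mann-Whitney
#' concordance probability with ties counted 1/2, and is identical to the
#' trapezoidal area under the returned curve.
#'
#' @param scores Numeric index values.
#' @param labels Logical (or 0/1) disease labels.
#' @return A list with `auc` and `curve`, a data.frame of
#'   `(fpr, tpr)` points from (0, 0) to (1, 1).
#' @export
roc_auc <- function(scores, labels) {
  d <- roc_prepare(scores, labels)
  pos <- d$scores[d$labels]
  neg <- d$scores[!d$labels]
  thr <- sort(unique(d$scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  # Mann-Whitney concordance, ties 1/2, via midranks (O(n log n))
  r <- rank(c(pos, neg))
  m <- length(pos); n <- length(neg)
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, curve = curve)
}

#' Youden-optimal cutoff
#'
#' Scans the observed score values as candidate inclusive (`>=`) cutoffs
#' and returns the one maximizing Youden's J = sensitivity + specificity
#' - 1.  Ties are broken toward the lower cutoff (higher sensitivity).
#' The reported cutoff is an observed value, not a midpoint.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  d <- roc_prepare(scores, labels)
  pos <- d$scores[d$labels]
  neg <- d$scores[!d$labels]
  cand <- sort(unique(d$scores))
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # candidates ascend, first max = lowest cutoff
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Full single-index ROC summary
#'
#' Combines [roc_auc()], [youden_cutoff()] and the DeLong variance of a
#' single empirical AUC into one result with a Wald 95% confidence
#' interval.
#'
#' @inheritParams roc_auc
#' @return A list of class `roc_result` with fields `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `cutoff`, `sensitivity`, `specificity`, `curve`, `n`.
#' @export
roc_analysis <- function(scores, labels) {
  d <- roc_prepare(scores, labels)
  ra <- roc_auc(d$scores, d$labels)
  yc <- youden_cutoff(d$scores, d$labels)
  v <- delong_auc_variance(d$scores, d$labels)
  half <- 1.959964 * sqrt(v)
  out <- list(
    auc = ra$auc,
    auc_ci_low = max(0, ra$auc - half),
    auc_ci_high = min(1, ra$auc + half),
    cutoff = yc$cutoff,
    sensitivity = yc$sensitivity,
    specificity = yc$specificity,
    j = yc$j,
    curve = ra$curve,
    n = length(d$scores),
    n_pos = sum(d$labels)
  )
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), n = %d (%d diseased)\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$n, x$n_pos))
  cat(sprintf("Youden cutoff >= %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
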
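# Structural components (placement values) of an empirical AUC:
# v10[i] = mean over non-diseased j of psi(x_i, y_j), v01[j] the dual,
# with psi = 1, 1/2, 0 for x > y, x = y, x < y.
delong_components <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = length(pos), n = length(neg))
}

# DeLong variance of a single empirical AUC.
delong_auc_variance <- function(scores, labels) {
  d <- roc_prepare(scores, labels)
  cp <- delong_components(d$scores, d$labels)
  s10 <- if (cp$m > 1) stats::var(cp$v10) else 0
  s01 <- if (cp$n > 1) stats::var(cp$v01) else 0
  s10 / cp$m + s01 / cp$n
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two diagnostic indices measured on the
#' same subjects, using the structural-components (placement-value)
#' estimator of the covariance matrix of the two empirical AUCs.  Subjects
#' missing either score are dropped pairwise.  The test statistic is
#' `z = (AUC_a - AUC_b) / sqrt(var)`, referred to the standard normal;
#' the 95% CI is Wald.  Two identical score vectors are reported as an
#' exact tie (`z = 0`, `p = 1`).
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param labels Logical (or 0/1) disease labels.
#' @return A list of class `delong_comparison` with `auc_a`, `auc_b`,
#'   `diff`, `var`, `z`, `p`, `ci_low`, `ci_high`, and the class sizes
#'   `m` (diseased) and `n` (non-diseased) after pairwise deletion.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort_invalid("scores_a, scores_b and labels must have equal length")
  }
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]
  labels <- as.logical(labels[ok])
  m <- sum(labels); n <- sum(!labels)
  if (m < 2 || n < 2) {
    abort_insufficient(
      "DeLong comparison needs >= 2 subjects per class after pairwise deletion")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(diff) <= .Machine$double.eps) 1 else 0
    v <- 0
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  half <- 1.959964 * sqrt(v)
  out <- list(auc_a = ca$auc, auc_b = cb$auc, diff = diff, var = v,
              z = z, p = p, ci_low = diff - half, ci_high = diff + half,
              m = m, n = n)
  class(out) <- "delong_comparison"
  out
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison (%d diseased / %d non-diseased)\n",
              x$m, x$n))
  cat(sprintf("  AUC A %.3f vs AUC B %.3f; difference %.3f (95%% CI %.3f-%.3f)\n",
              x$auc_a, x$auc_b, x$diff, x$ci_low, x$ci_high))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}
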
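#' Paired t and Wilcoxon signed-rank tests
#'
#' Computes both pre/post comparison statistics on the paired differences
#' `pre - post`.  The t statistic is `mean(d) / (sd(d) / sqrt(n))` on
#' `n - 1` degrees of freedom.  For the signed-rank test, zero differences
#' are dropped (Wilcoxon convention) and absolute differences are ranked
#' with average ties; the null distribution is exact for `n <= 25`
#' (conditional on the observed midranks, so ties are handled exactly),
#' otherwise a normal approximation with tie correction is used.
#' All p-values are two-sided.
#'
#' Degenerate inputs are flagged rather than failing: all-zero
#' differences give `p = 1` for the signed-rank test and an undefined t;
#' constant non-zero differences give an undefined t (zero variance) with
#' the signed-rank test still exact.
#'
#' @param pre,post Equal-length paired numeric vectors; incomplete pairs
#'   are dropped.
#' @return A list of class `paired_tests` with elements `n`, `mean_diff`,
#'   `direction` (`"decrease"`, `"increase"` or `"none"`), `t`
#'   (`statistic`, `df`, `p`), `wilcoxon` (`statistic`, `p`, `exact`),
#'   and `degenerate`.
#' @export
paired_tests <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort_invalid("pre and post must have equal length")
  }
  ok <- !is.na(pre) & !is.na(post)
  d <- pre[ok] - post[ok]
  n <- length(d)
  if (n < 5) abort_insufficient("paired tests need >= 5 complete pairs")

  mean_d <- mean(d)
  sd_d <- sd(d)
  degenerate <- all(d == 0)
  if (sd_d == 0) {
    t_res <- list(statistic = NA_real_, df = n - 1, p = NA_real_)
  } else {
    tstat <- mean_d / (sd_d / sqrt(n))
    t_res <- list(statistic = tstat, df = n - 1,
                  p = 2 * pt(-abs(tstat), df = n - 1))
  }
  w_res <- signed_rank_test(d)

  out <- list(
    n = n,
    mean_diff = mean_d,
    direction = if (mean_d > 0) "decrease" else if (mean_d < 0) "increase" else "none",
    t = t_res,
    wilcoxon = w_res,
    degenerate = degenerate
  )
  class(out) <- "paired_tests"
  out
}

# Wilcoxon signed-rank on a vector of differences.
signed_rank_test <- function(d) {
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0) {
    return(list(statistic = NA_real_, p = 1, exact = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (nz <= 25) {
    # exact two-sided p from the conditional null over all 2^n sign
    # assignments, via a generating-function convolution on the doubled
    # midranks (integers even under ties)
    w <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(w)))  # counts[s + 1] = #subsets with sum s
    for (wi in w) {
      shifted <- c(rep(0, wi), counts[seq_len(length(counts) - wi)])
      counts <- counts + shifted
    }
    total <- 2^nz
    v2 <- as.integer(round(2 * v))
    mu2 <- sum(w) / 2
    p <- if (v2 > mu2) {
      2 * sum(counts[(v2 + 1):length(counts)]) / total
    } else if (v2 < mu2) {
      2 * sum(counts[1:(v2 + 1)]) / total
    } else 1
    p <- min(1, p)
    list(statistic = v, p = p, exact = TRUE)
  } else {
    mu <- nz * (nz + 1) / 4
    tie_sizes <- table(abs(d))
    sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (v - mu) / sqrt(sig2)
    list(statistic = v, p = 2 * pnorm(-abs(z)), exact = FALSE)
  }
}

#' @export
print.paired_tests <- function(x, ...) {
  cat(sprintf("Paired comparison, n = %d complete pairs (%s)\n",
              x$n, x$direction))
  if (is.na(x$t$statistic)) {
    cat("  paired t: undefined (zero variance of differences)\n")
  } else {
    cat(sprintf("  paired t: t = %.3f, df = %d, p = %.4g\n",
                x$t$statistic, x$t$df, x$t$p))
  }
  cat(sprintf("  Wilcoxon signed-rank: V = %s, p = %.4g (%s)\n",
              format(x$wilcoxon$statistic), x$wilcoxon$p,
              if (x$wilcoxon$exact) "exact" else "normal approximation"))
  invisible(x)
}
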
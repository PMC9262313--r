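#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-ranked data (ties share the mean rank);
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Incomplete pairs are dropped pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `rho`, `p`, and `n` (complete pairs used).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort_insufficient("Spearman correlation needs >= 3 complete pairs")
  # values constant to numerical precision carry no ranking information
  near_const <- function(v) diff(range(v)) <= 1e-9 * max(1, max(abs(v)))
  if (near_const(x) || near_const(y)) {
    abort_undefined("correlation undefined: zero rank variance")
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort_undefined("correlation undefined: zero rank variance")
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
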
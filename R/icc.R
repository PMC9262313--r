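#' Intraclass correlation for measurement reproducibility
#'
#' Two-way random-effects single-measures ICC from the two-way ANOVA mean
#' squares of a complete subjects-by-raters table.  The default
#' `"agreement"` form (ICC(A,1)) penalizes systematic offsets between
#' raters:
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' where MS_R, MS_C and MS_E are the subject, rater and residual mean
#' squares.  The `"consistency"` form (ICC(C,1)) drops the rater
#' variance term.
#'
#' @param ratings Numeric matrix or data.frame, one row per subject, one
#'   column per rater (or session); complete, >= 5 subjects, >= 2 raters.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return A list of class `icc_result` with `icc`, `model`,
#'   `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  if (any(is.na(m))) abort_insufficient("ICC requires a complete ratings table")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) abort_insufficient("ICC requires >= 5 subjects")
  if (k < 2) abort_insufficient("ICC requires >= 2 raters")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))

  icc <- if (type == "agreement") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  }
  out <- list(
    icc = icc,
    model = sprintf("two-way, %s, single measures",
                    if (type == "agreement") "absolute agreement" else "consistency"),
    n_subjects = n,
    n_raters = k
  )
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f (%s; %d subjects, %d raters)\n",
              x$icc, x$model, x$n_subjects, x$n_raters))
  invisible(x)
}
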
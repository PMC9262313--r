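index_labels <- c(
  spap_lvidd = "sPAP_Echo/LVIDd",
  mpap_lvidd = "mPAP_Echo/LVIDd",
  abbas_index = "TRV^2/TVI_RVOT"
)

# Run `expr`, converting a classed package error into a skipped-block
# record so the pipeline always completes with an auditable reason.
as_block <- function(expr) {
  tryCatch(
    c(list(status = "ok"), expr),
    echopvr_error = function(e) list(status = "skipped", reason = conditionMessage(e))
  )
}

moment_row <- function(x) {
  x <- x[!is.na(x)]
  list(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
}

#' Baseline diagnostic evaluation of the echocardiographic indices
#'
#' On the pre-treatment rows of a cohort: derives the indices (if not
#' already derived), then for each of sPAP_Echo/LVIDd, mPAP_Echo/LVIDd
#' and TRV^2/TVI_RVOT computes the Spearman correlation against invasive
#' PVR, the empirical ROC with DeLong CI and Youden cutoff for detecting
#' PVR above `pvr_threshold`, and all pairwise DeLong AUC comparisons on
#' pairwise-complete subjects.  Missingness is accounted per index; an
#' index whose correlation or ROC cannot be formed (single class, zero
#' variance, too few pairs) is reported as skipped with the reason.
#'
#' @param cohort Cohort data.frame (raw or already derived).
#' @param pvr_threshold Severity threshold, dyn.s.cm^-5 (default 1000).
#' @param indices Derived-index columns to evaluate.
#' @return A list with `cohort_summary`, `correlation`, `roc` blocks.
#' @export
run_baseline_analysis <- function(cohort, pvr_threshold = 1000,
                                  indices = names(index_labels)) {
  n_input <- nrow(cohort)
  if (!all(derived_columns %in% names(cohort))) {
    cohort <- derive_indices(cohort, pvr_threshold = pvr_threshold)
  }
  pre <- cohort[cohort$timepoint == "pre", , drop = FALSE]
  n_pre <- nrow(pre)

  summary_block <- list(
    n_input_rows = n_input,
    n_pre = n_pre,
    n_excluded_non_pre = n_input - n_pre,
    missingness = list(
      trv = mean(is.na(pre$trv_ms)),
      prv = mean(is.na(pre$prv_ms)),
      tvi_rvot = mean(is.na(pre$tvi_rvot_cm))
    ),
    moments = lapply(
      c(mpap_rhc = "mpap_rhc", spap_rhc = "spap_rhc", pcwp = "pcwp",
        pvr = "pvr", lvidd_mm = "lvidd_mm", spap_echo = "spap_echo",
        mpap_echo = "mpap_echo", spap_lvidd = "spap_lvidd",
        mpap_lvidd = "mpap_lvidd", abbas_index = "abbas_index"),
      function(v) moment_row(pre[[v]])),
    high_pvr_fraction = mean(pre$high_pvr, na.rm = TRUE)
  )

  correlation <- lapply(indices, function(ix) {
    b <- as_block(spearman_rho(pre[[ix]], pre$pvr))
    b$index <- unname(index_labels[ix])
    b$n_missing <- sum(is.na(pre[[ix]]) | is.na(pre$pvr))
    b
  })
  names(correlation) <- indices

  roc <- lapply(indices, function(ix) {
    ok <- !is.na(pre[[ix]]) & !is.na(pre$high_pvr)
    b <- as_block(unclass(roc_analysis(pre[[ix]][ok], pre$high_pvr[ok])))
    b$index <- unname(index_labels[ix])
    b$n_missing <- sum(!ok)
    b
  })
  names(roc) <- indices

  pairs <- utils::combn(indices, 2, simplify = FALSE)
  delong <- lapply(pairs, function(pr) {
    b <- as_block(unclass(delong_test(pre[[pr[1]]], pre[[pr[2]]], pre$high_pvr)))
    b$index_a <- unname(index_labels[pr[1]])
    b$index_b <- unname(index_labels[pr[2]])
    b
  })
  names(delong) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  list(cohort_summary = summary_block, correlation = correlation,
       roc = c(roc, list(delong = delong)))
}

#' Paired pre/post-endarterectomy analysis
#'
#' Pairs `pre` and `post` rows by patient, runs paired t and Wilcoxon
#' signed-rank tests on every hemodynamic and echocardiographic quantity
#' in the schema, computes per-patient reduction rates for the two
#' pressure/LVIDd indices and PVR, and the Spearman correlation between
#' each index reduction rate and the PVR reduction rate.  Unpaired rows
#' are excluded with a logged count.
#'
#' @inheritParams run_baseline_analysis
#' @return A list with pairing accounting, `paired_comparisons`,
#'   `reduction_rates` and `delta_correlations`.
#' @export
run_pea_analysis <- function(cohort, pvr_threshold = 1000) {
  n_input <- nrow(cohort)
  if (!all(derived_columns %in% names(cohort))) {
    cohort <- derive_indices(cohort, pvr_threshold = pvr_threshold)
  }
  pre <- cohort[cohort$timepoint == "pre", , drop = FALSE]
  post <- cohort[cohort$timepoint == "post", , drop = FALSE]
  ids <- intersect(pre$patient_id, post$patient_id)
  n_excluded <- n_input - 2 * length(ids)
  if (n_excluded > 0) {
    message(sprintf("run_pea_analysis: excluded %d unpaired row(s)", n_excluded))
  }
  if (length(ids) < 5) {
    return(list(status = "skipped",
                reason = "fewer than 5 patients with both timepoints",
                n_input_rows = n_input, n_pairs = length(ids),
                n_excluded = n_excluded))
  }
  pre <- pre[match(ids, pre$patient_id), ]
  post <- post[match(ids, post$patient_id), ]

  quantities <- c("mpap_rhc", "pvr", "lvidd_mm", "trv_ms", "spap_echo",
                  "prv_ms", "mpap_echo", "tvi_rvot_cm",
                  "abbas_index", "mpap_lvidd", "spap_lvidd")
  paired <- lapply(quantities, function(v) {
    b <- as_block(unclass(paired_tests(pre[[v]], post[[v]])))
    b$pre_mean <- mean(pre[[v]], na.rm = TRUE)
    b$post_mean <- mean(post[[v]], na.rm = TRUE)
    b
  })
  names(paired) <- quantities

  rr <- function(v) reduction_rate(pre[[v]], post[[v]])
  reductions <- list(
    pvr = moment_row(rr("pvr")),
    spap_lvidd = moment_row(rr("spap_lvidd")),
    mpap_lvidd = moment_row(rr("mpap_lvidd"))
  )
  delta <- lapply(c(spap_lvidd = "spap_lvidd", mpap_lvidd = "mpap_lvidd"),
                  function(v) as_block(spearman_rho(rr(v), rr("pvr"))))

  list(status = "ok", n_input_rows = n_input, n_pairs = length(ids),
       n_excluded = n_excluded, paired_comparisons = paired,
       reduction_rates = reductions, delta_correlations = delta)
}

#' Reproducibility (ICC) analysis of duplicate measurements
#'
#' Computes the intraclass correlation (two-way, absolute agreement,
#' single measures by default) for each measurement with duplicate
#' observation columns `<measure>_obs1` / `<measure>_obs2`, e.g. as
#' produced by [generate_repeats()] or recorded by two observers.
#'
#' @param repeats Data frame of duplicate measurements.
#' @param measures Measurement names; by default inferred from the
#'   `_obs1`/`_obs2` column pairs present.
#' @param type ICC form, see [icc_agreement()].
#' @return A named list of ICC blocks (one per measurement).
#' @export
run_reliability <- function(repeats, measures = NULL,
                            type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (is.null(measures)) {
    o1 <- sub("_obs1$", "", grep("_obs1$", names(repeats), value = TRUE))
    o2 <- sub("_obs2$", "", grep("_obs2$", names(repeats), value = TRUE))
    measures <- intersect(o1, o2)
  }
  if (!length(measures)) {
    return(list(status = "skipped", reason = "no duplicate measurement columns"))
  }
  out <- lapply(measures, function(m) {
    tab <- repeats[, paste0(m, c("_obs1", "_obs2"))]
    as_block(unclass(icc_agreement(tab, type = type)))
  })
  names(out) <- measures
  c(list(status = "ok"), out)
}

#' Full analysis report for a cohort
#'
#' Runs the baseline evaluation, the paired pre/post analysis (when both
#' timepoints are present) and the reproducibility analysis (when a
#' repeats table is supplied), returning one serializable report.
#' Running the pipeline twice on identical inputs yields identical
#' reports: no stage uses random numbers.
#'
#' @inheritParams run_baseline_analysis
#' @param repeats Optional duplicate-measurements table for
#'   [run_reliability()].
#' @return A list of class `echopvr_report`.
#' @export
analyze_cohort <- function(cohort, repeats = NULL, pvr_threshold = 1000) {
  report <- list(
    baseline = run_baseline_analysis(cohort, pvr_threshold = pvr_threshold),
    pea = if (any(cohort$timepoint == "post")) {
      run_pea_analysis(cohort, pvr_threshold = pvr_threshold)
    } else {
      list(status = "skipped", reason = "no post-treatment rows")
    },
    reliability = if (!is.null(repeats)) run_reliability(repeats) else
      list(status = "skipped", reason = "no repeats table supplied")
  )
  class(report) <- "echopvr_report"
  report
}

#' Write an analysis report as JSON
#'
#' @param report An `echopvr_report` (or any list).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.echopvr_report <- function(x, ...) {
  s <- x$baseline$cohort_summary
  cat(sprintf("CTEPH cohort analysis: %d pre-treatment records\n", s$n_pre))
  cat(sprintf("  high-PVR fraction: %.1f%%; TR missing %.1f%%, PR missing %.1f%%\n",
              100 * s$high_pvr_fraction, 100 * s$missingness$trv,
              100 * s$missingness$prv))
  for (ix in names(index_labels)) {
    co <- x$baseline$correlation[[ix]]
    ro <- x$baseline$roc[[ix]]
    if (identical(co$status, "ok")) {
      cat(sprintf("  %-16s rho = %.2f (p = %.3g, n = %d)",
                  index_labels[ix], co$rho, co$p, co$n))
    } else {
      cat(sprintf("  %-16s correlation skipped: %s", index_labels[ix], co$reason))
    }
    if (identical(ro$status, "ok")) {
      cat(sprintf("; AUC = %.3f, cutoff >= %.3g (sens %.1f%%, spec %.1f%%)\n",
                  ro$auc, ro$cutoff, 100 * ro$sensitivity, 100 * ro$specificity))
    } else {
      cat(sprintf("; ROC skipped: %s\n", ro$reason))
    }
  }
  if (identical(x$pea$status, "ok")) {
    cat(sprintf("  pre/post pairs: %d; mean PVR reduction %.1f%%\n",
                x$pea$n_pairs, x$pea$reduction_rates$pvr$mean))
  }
  invisible(x)
}
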
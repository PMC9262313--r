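cohort_columns <- c(
  "patient_id", "timepoint", "trv_ms", "prv_ms", "tvi_rvot_cm", "lvidd_mm",
  "ivc_diam_cm", "ivc_collapse", "spap_rhc", "mpap_rhc", "rap_rhc", "pcwp",
  "co_lmin", "bsa_m2"
)

derived_columns <- c(
  "rap_echo", "spap_echo", "mpap_echo", "spap_lvidd", "mpap_lvidd",
  "abbas_index", "tpg", "pvr_wood", "pvr", "high_pvr"
)

#' Read a cohort CSV
#'
#' One row per patient-timepoint, UTF-8 with a header; empty cells are
#' missing values.  The required columns are `patient_id`, `timepoint`
#' (`pre`/`post`), `trv_ms`, `prv_ms`, `tvi_rvot_cm`, `lvidd_mm`,
#' `ivc_diam_cm`, `ivc_collapse`, `spap_rhc`, `mpap_rhc`, `rap_rhc`,
#' `pcwp`, `co_lmin`, `bsa_m2`; extra columns are passed through.
#'
#' @param path CSV file path.
#' @param validate Check the physiological invariants on read (default TRUE).
#' @return A data.frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols)) {
    abort_invalid(paste("cohort CSV lacks required columns:",
                        paste(missing_cols, collapse = ", ")))
  }
  if (validate) validate_cohort(df)
  df
}

#' Write a cohort (or derived) table as CSV
#'
#' @param cohort Data frame in the cohort dialect.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate cohort physiological invariants
#'
#' Checks that present Doppler velocities lie in (0, 7) m/s, LVIDd in
#' (20, 80) mm, IVC collapse in `[0, 1]`, `mpap_rhc <= spap_rhc`,
#' `pcwp >= 0`, `co_lmin > 0`, and that pre-timepoint (CTEPH-qualifying)
#' records satisfy `mpap_rhc >= 25` and `pcwp <= 15`.
#'
#' @param cohort Cohort data.frame.
#' @return The cohort, invisibly; stops on the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  chk <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) abort_invalid(msg)
  }
  chk(!cohort$timepoint %in% c("pre", "post"),
      "timepoint must be 'pre' or 'post'")
  for (v in c("trv_ms", "prv_ms")) {
    chk(cohort[[v]] <= 0 | cohort[[v]] >= 7,
        sprintf("%s must lie in (0, 7) m/s where present", v))
  }
  chk(cohort$lvidd_mm <= 20 | cohort$lvidd_mm >= 80,
      "lvidd_mm must lie in (20, 80) mm")
  chk(cohort$ivc_collapse < 0 | cohort$ivc_collapse > 1,
      "ivc_collapse must lie in [0, 1]")
  chk(cohort$mpap_rhc > cohort$spap_rhc, "mpap_rhc must not exceed spap_rhc")
  chk(cohort$pcwp < 0, "pcwp must be non-negative")
  chk(cohort$co_lmin <= 0, "co_lmin must be positive")
  pre <- cohort$timepoint == "pre"
  chk(pre & cohort$mpap_rhc < 25,
      "CTEPH-qualifying (pre) records require mpap_rhc >= 25 mmHg")
  chk(pre & cohort$pcwp > 15,
      "CTEPH-qualifying (pre) records require pcwp <= 15 mmHg")
  invisible(cohort)
}

#' Derive indices for every row of a cohort table
#'
#' Vectorised counterpart of [derive_all()]: appends the derived-index
#' columns (`rap_echo`, `spap_echo`, `mpap_echo`, `spap_lvidd`,
#' `mpap_lvidd`, `abbas_index`, `tpg`, `pvr_wood`, `pvr`, `high_pvr`)
#' to the cohort.  When both `echo_date` and `rhc_date` columns are
#' present, rows whose acquisition dates differ by more than
#' `max_pairing_days` are dropped with a message (the study's pairing
#' rule); otherwise all rows are kept.
#'
#' @inheritParams derive_all
#' @param cohort Cohort data.frame (see [read_cohort()]).
#' @param max_pairing_days Maximum allowed echo-RHC interval in days.
#' @return The cohort with derived columns appended; attribute
#'   `n_excluded` counts rows dropped by the pairing rule.
#' @export
derive_indices <- function(cohort, pvr_threshold = 1000, trv_ceiling = 6,
                           max_pairing_days = 3) {
  n_excluded <- 0L
  if (all(c("echo_date", "rhc_date") %in% names(cohort))) {
    gap <- abs(as.numeric(as.Date(cohort$echo_date) - as.Date(cohort$rhc_date)))
    keep <- is.na(gap) | gap <= max_pairing_days
    n_excluded <- sum(!keep)
    if (n_excluded > 0) {
      message(sprintf(
        "derive_indices: excluded %d row(s) with echo-RHC interval > %d days",
        n_excluded, max_pairing_days))
      cohort <- cohort[keep, , drop = FALSE]
    }
  }
  n_flag <- sum(cohort$trv_ms > trv_ceiling, na.rm = TRUE)
  if (n_flag > 0) {
    warning(sprintf(
      "%d TRV value(s) exceed %.1f m/s: possible severe-TR overestimation",
      n_flag, trv_ceiling), call. = FALSE)
  }
  rap <- estimate_rap_from_ivc(cohort$ivc_diam_cm, cohort$ivc_collapse)
  sp <- spap_echo(cohort$trv_ms, rap)
  mp <- mpap_echo(cohort$prv_ms, rap)
  tpg <- transpulmonary_gradient(cohort$mpap_rhc, cohort$pcwp)
  pvr <- pvr_dyn(tpg, cohort$co_lmin)
  cohort$rap_echo <- rap
  cohort$spap_echo <- sp
  cohort$mpap_echo <- mp
  cohort$spap_lvidd <- pressure_lvidd_index(sp, cohort$lvidd_mm)
  cohort$mpap_lvidd <- pressure_lvidd_index(mp, cohort$lvidd_mm)
  cohort$abbas_index <- abbas_index(cohort$trv_ms, cohort$tvi_rvot_cm)
  cohort$tpg <- tpg
  cohort$pvr_wood <- pvr / 80
  cohort$pvr <- pvr
  cohort$high_pvr <- pvr > pvr_threshold
  attr(cohort, "n_excluded") <- n_excluded
  cohort
}
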
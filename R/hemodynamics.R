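#' Estimate right atrial pressure from the inferior vena cava
#'
#' Maps IVC diameter and inspiratory collapse to the guideline three-level
#' right atrial pressure score: a small IVC (diameter at or below
#' `diameter_threshold`) that collapses by more than `collapse_threshold`
#' scores 3 mmHg, a dilated IVC with blunted collapse scores 15 mmHg, and
#' discordant size/collapse patterns score the intermediate 8 mmHg.
#'
#' @param diameter IVC end-expiratory diameter in cm.
#' @param collapse Inspiratory collapse fraction in `[0, 1]`.
#' @param diameter_threshold Diameter cutpoint in cm (default 2.1).
#' @param collapse_threshold Collapse cutpoint (default 0.5).
#' @return Estimated RAP in mmHg, one of 3, 8 or 15; `NA` where either
#'   input is `NA`.
#' @examples
#' estimate_rap_from_ivc(1.8, 0.6)  # 3
#' estimate_rap_from_ivc(2.5, 0.2)  # 15
#' estimate_rap_from_ivc(2.5, 0.6)  # 8
#' @export
estimate_rap_from_ivc <- function(diameter, collapse,
                                  diameter_threshold = 2.1,
                                  collapse_threshold = 0.5) {
  ok <- !is.na(diameter) & !is.na(collapse)
  if (any(diameter[ok] <= 0)) {
    abort_invalid("IVC diameter must be positive")
  }
  if (any(collapse[ok] < 0 | collapse[ok] > 1)) {
    abort_invalid("IVC collapse fraction must lie in [0, 1]")
  }
  small <- diameter <= diameter_threshold
  brisk <- collapse > collapse_threshold
  rap <- ifelse(small & brisk, 3, ifelse(!small & !brisk, 15, 8))
  rap[!ok] <- NA_real_
  rap
}

#' Systolic pulmonary artery pressure from the tricuspid jet
#'
#' Simplified Bernoulli estimate `4 * TRV^2 + RAP`.  A missing tricuspid
#' regurgitation velocity propagates to a missing result.
#'
#' @param trv Peak tricuspid regurgitation velocity, m/s.
#' @param rap Estimated right atrial pressure, mmHg (3, 8 or 15).
#' @return Estimated systolic PAP in mmHg.
#' @export
spap_echo <- function(trv, rap) {
  check_velocity(trv, "TRV")
  check_rap(rap)
  4 * trv^2 + rap
}

#' Mean pulmonary artery pressure from the pulmonary regurgitant jet
#'
#' Simplified Bernoulli estimate `4 * PRV^2 + RAP` from the peak
#' early-diastolic pulmonary regurgitation velocity.
#'
#' @param prv Early-diastolic pulmonary regurgitation velocity, m/s.
#' @inheritParams spap_echo
#' @return Estimated mean PAP in mmHg.
#' @export
mpap_echo <- function(prv, rap) {
  check_velocity(prv, "PRV")
  check_rap(rap)
  4 * prv^2 + rap
}

check_velocity <- function(v, what) {
  bad <- !is.na(v) & v <= 0
  if (any(bad)) abort_invalid(sprintf("%s must be positive", what))
  invisible(v)
}

check_rap <- function(rap) {
  bad <- !is.na(rap) & !(rap %in% c(3, 8, 15))
  if (any(bad)) abort_invalid("RAP must be one of 3, 8 or 15 mmHg")
  invisible(rap)
}

#' Pressure-to-LV-diameter screening index
#'
#' Ratio of an echocardiographic pulmonary artery pressure estimate to the
#' LV internal diameter at end-diastole.  The same operation serves both
#' sPAP_Echo/LVIDd and mPAP_Echo/LVIDd; the diameter acts as a surrogate
#' for pulmonary blood flow (LV underfilling under RV pressure overload).
#'
#' @param pressure sPAP_Echo or mPAP_Echo, mmHg.
#' @param lvidd LV internal diameter at end-diastole, mm.
#' @return Index in mmHg/mm.
#' @export
pressure_lvidd_index <- function(pressure, lvidd) {
  if (any(!is.na(lvidd) & lvidd <= 0)) {
    abort_invalid("LVIDd must be positive")
  }
  if (any(!is.na(pressure) & pressure <= 0)) {
    abort_invalid("pressure must be positive")
  }
  pressure / lvidd
}

#' Tricuspid-velocity to RVOT flow index
#'
#' The comparator index `TRV^2 / TVI_RVOT` (Abbas), pairing the squared
#' tricuspid jet velocity with the RV outflow-tract velocity-time integral.
#'
#' @param trv Peak tricuspid regurgitation velocity, m/s.
#' @param tvi_rvot RV outflow tract velocity-time integral, cm.
#' @return Index in (m/s)^2/cm.
#' @export
abbas_index <- function(trv, tvi_rvot) {
  check_velocity(trv, "TRV")
  if (any(!is.na(tvi_rvot) & tvi_rvot <= 0)) {
    abort_invalid("TVI_RVOT must be positive")
  }
  trv^2 / tvi_rvot
}

#' Transpulmonary gradient
#'
#' `mPAP - PCWP`.  A non-positive gradient is physiologically implausible
#' in precapillary pulmonary hypertension; it is returned with a warning
#' rather than an error.
#'
#' @param mpap Mean pulmonary artery pressure, mmHg.
#' @param pcwp Pulmonary capillary wedge pressure, mmHg.
#' @return TPG in mmHg.
#' @export
transpulmonary_gradient <- function(mpap, pcwp) {
  tpg <- mpap - pcwp
  if (any(!is.na(tpg) & tpg <= 0)) {
    warning("non-positive transpulmonary gradient: implausible for CTEPH",
            call. = FALSE)
  }
  tpg
}

#' Pulmonary vascular resistance
#'
#' `pvr_wood()` returns TPG/CO in Wood units; `pvr_dyn()` converts to
#' dyn.s.cm^-5 (1 Wood unit = 80 dyn.s.cm^-5), the unit used for the
#' severity threshold of 1000 dyn.s.cm^-5.
#'
#' @param tpg Transpulmonary gradient, mmHg.
#' @param co Cardiac output, L/min.
#' @return Resistance in the stated unit.
#' @export
pvr_dyn <- function(tpg, co) {
  80 * pvr_wood(tpg, co)
}

#' @rdname pvr_dyn
#' @export
pvr_wood <- function(tpg, co) {
  if (any(!is.na(co) & co <= 0)) {
    abort_invalid("cardiac output must be positive")
  }
  tpg / co
}

#' Cardiac output from Fick cardiac index
#'
#' `CO = CI x BSA`; the Fick measurement itself is an input, not computed.
#'
#' @param ci Cardiac index, L/min/m^2.
#' @param bsa Body surface area, m^2.
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(ci, bsa) {
  if (any(!is.na(ci) & ci <= 0) || any(!is.na(bsa) & bsa <= 0)) {
    abort_invalid("cardiac index and BSA must be positive")
  }
  ci * bsa
}

#' Threshold classification of an index value
#'
#' Inclusive rule `value >= cutoff`, matching the published cutpoints
#' (sPAP_Echo/LVIDd >= 1.94, mPAP_Echo/LVIDd >= 0.97).
#'
#' @param value Index value(s).
#' @param cutoff Classification cutoff.
#' @return Logical.
#' @export
classify_high_pvr <- function(value, cutoff) {
  value >= cutoff
}

#' Relative reduction rate
#'
#' Percent decrease from a pre-intervention to a post-intervention value:
#' `100 * (pre - post) / pre`.  Used for the pre/post-endarterectomy delta
#' analysis (positive when the quantity falls).
#'
#' @param pre_value Pre-intervention value (> 0).
#' @param post_value Post-intervention value.
#' @return Reduction in percent.
#' @export
reduction_rate <- function(pre_value, post_value) {
  if (any(!is.na(pre_value) & pre_value <= 0)) {
    abort_invalid("pre-intervention value must be positive")
  }
  100 * (pre_value - post_value) / pre_value
}

#' Derive all indices for one patient-timepoint
#'
#' Composes the elementary operations into the full derived record:
#' echo-estimated RAP, sPAP_Echo, mPAP_Echo, both pressure/LVIDd indices,
#' TRV^2/TVI_RVOT, TPG, PVR (Wood and dyn.s.cm^-5) and the invasive
#' high-PVR label (PVR > `pvr_threshold`).  Optional Doppler signals that
#' are missing (no measurable TR or PR jet) yield missing dependent
#' indices; nothing is imputed.
#'
#' @param echo A list or one-row data.frame with fields `patient_id`,
#'   `timepoint`, `trv` (m/s, may be `NA`), `prv` (m/s, may be `NA`),
#'   `tvi_rvot` (cm, may be `NA`), `lvidd` (mm), `ivc_diameter` (cm),
#'   `ivc_collapse` (fraction).
#' @param rhc A list or one-row data.frame with fields `patient_id`,
#'   `timepoint`, `spap_rhc`, `mpap_rhc`, `rap_rhc`, `pcwp` (mmHg),
#'   `co` (L/min) and optionally `bsa` (m^2).
#' @param pvr_threshold Severity threshold in dyn.s.cm^-5 (default 1000).
#' @param trv_ceiling TRV above this (m/s) is flagged with a warning as a
#'   possible severe-TR overestimate (default 6); no correction is applied.
#' @return A list of class `derived_indices`.
#' @export
derive_all <- function(echo, rhc, pvr_threshold = 1000, trv_ceiling = 6) {
  echo <- as.list(echo)
  rhc <- as.list(rhc)
  if (!identical(as.character(echo$patient_id), as.character(rhc$patient_id)) ||
      !identical(as.character(echo$timepoint), as.character(rhc$timepoint))) {
    abort_pairing("echo and RHC records do not belong to the same patient-timepoint")
  }
  if (!is.na(echo$trv) && echo$trv > trv_ceiling) {
    warning(sprintf(
      "TRV %.2f m/s exceeds %.1f m/s: possible severe-TR overestimation",
      echo$trv, trv_ceiling), call. = FALSE)
  }
  rap <- estimate_rap_from_ivc(echo$ivc_diameter, echo$ivc_collapse)
  sp <- spap_echo(echo$trv, rap)
  mp <- mpap_echo(echo$prv, rap)
  tpg <- transpulmonary_gradient(rhc$mpap_rhc, rhc$pcwp)
  pvr <- pvr_dyn(tpg, rhc$co)
  out <- list(
    patient_id = echo$patient_id,
    timepoint = echo$timepoint,
    rap_echo = rap,
    spap_echo = sp,
    mpap_echo = mp,
    spap_lvidd = if (is.na(sp)) NA_real_ else pressure_lvidd_index(sp, echo$lvidd),
    mpap_lvidd = if (is.na(mp)) NA_real_ else pressure_lvidd_index(mp, echo$lvidd),
    abbas_index = abbas_index(echo$trv, echo$tvi_rvot),
    tpg = tpg,
    pvr_wood = pvr / 80,
    pvr = pvr,
    high_pvr = pvr > pvr_threshold
  )
  class(out) <- "derived_indices"
  out
}

#' @export
print.derived_indices <- function(x, ...) {
  cat(sprintf("Derived indices for patient %s (%s)\n", x$patient_id, x$timepoint))
  fmt <- function(v) if (is.na(v)) "  --" else sprintf("%7.2f", v)
  cat(sprintf("  RAP (echo)        %s mmHg\n", fmt(x$rap_echo)))
  cat(sprintf("  sPAP_Echo         %s mmHg\n", fmt(x$spap_echo)))
  cat(sprintf("  mPAP_Echo         %s mmHg\n", fmt(x$mpap_echo)))
  cat(sprintf("  sPAP_Echo/LVIDd   %s mmHg/mm\n", fmt(x$spap_lvidd)))
  cat(sprintf("  mPAP_Echo/LVIDd   %s mmHg/mm\n", fmt(x$mpap_lvidd)))
  cat(sprintf("  TRV^2/TVI_RVOT    %s (m/s)^2/cm\n", fmt(x$abbas_index)))
  cat(sprintf("  TPG               %s mmHg\n", fmt(x$tpg)))
  cat(sprintf("  PVR               %s dyn.s.cm^-5 (%s WU)%s\n",
              fmt(x$pvr), fmt(x$pvr_wood),
              if (isTRUE(x$high_pvr)) "  [high PVR]" else ""))
  invisible(x)
}
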
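#' Configuration for the synthetic CTEPH cohort generator
#'
#' Returns the full parameterization of the generator, calibrated to the
#' published baseline cohort profile: mPAP 43.7 +/- 10.8 mmHg (truncated at
#' the diagnostic floor of 25 mmHg, with the pre-truncation location solved
#' so the realized mean equals `mpap_mean`), PCWP 8.4 +/- 3.8 mmHg in
#' `[1, 15]`, PVR with mean ~987 and ~41% above 1000 dyn.s.cm^-5,
#' LVIDd ~41.5 +/- 5.2 mm with negative PVR coupling (LV underfilling),
#' sPAP/mPAP ratio 1.81, TR/PR signal obtainability 89%/58.3%, and a
#' pre-to-post endarterectomy PVR reduction of 48% +/- 15%.
#'
#' Cardiac index is modeled as severity-coupled
#' (`ci = ci_mean + ci_mpap_slope * z_mpap + noise`, clamped to
#' `ci_range`): the published PVR distribution is reproducible under the
#' TPG/CO construction only when flow falls with severity, so the PVR
#' moments - not the printed cardiac-index row, whose dispersion is
#' implausible as printed - anchor the flow calibration.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; all stages draw from sub-streams derived from
#'   it, so adding a stage does not reshuffle earlier ones.
#' @param mpap_mean,mpap_sd Mean PAP moments, mmHg.
#' @param pcwp_mean,pcwp_sd Wedge pressure moments, mmHg (truncated `[1,15]`).
#' @param ci_mean,ci_sd Cardiac-index conditional location and residual SD,
#'   L/min/m^2.
#' @param ci_mpap_slope Change in CI per SD of mPAP (L/min/m^2; negative).
#' @param ci_range Clamp range for CI.
#' @param bsa_mean,bsa_sd Body surface area moments, m^2.
#' @param spap_over_mpap Systolic-to-mean PAP ratio.
#' @param spap_noise_sd SD of sPAP around `spap_over_mpap * mPAP`, mmHg.
#' @param lvidd_base_mm,lvidd_pvr_slope,lvidd_noise_sd LVIDd coupling:
#'   `lvidd = base + slope * z_pvr + noise` (mm; slope negative).
#' @param tvi_base_cm,tvi_pvr_slope,tvi_noise_sd Same coupling for
#'   TVI_RVOT (cm).
#' @param velocity_noise_sd Measurement noise on TRV/PRV, m/s.
#' @param rap_shift Severity shift of the latent RAP score per SD of PVR.
#' @param rap_noise_scale Logistic noise scale of the latent RAP score;
#'   0 makes the RAP category deterministic in PVR.
#' @param rap_cutpoints Two latent cutpoints separating RAP 3 / 8 / 15.
#' @param pvr_ref_mean,pvr_ref_sd Reference moments used to standardize PVR
#'   in the couplings (dyn.s.cm^-5).
#' @param p_tr_obtainable,p_pr_obtainable Probability that the TR / PR
#'   Doppler signal is measurable.
#' @param pea_pvr_reduction_mean,pea_pvr_reduction_sd Fractional PVR
#'   reduction after endarterectomy (truncated to `[0.05, 0.9]`).
#' @param pea_tpg_share Share of the PVR fall carried by the pressure side:
#'   post TPG = pre TPG x (1-r)^share, post CO = pre CO x (1-r)^(share-1),
#'   so the PVR identity holds exactly and CO rises.
#' @param rhc_noise_sd Measurement noise added to the invasive pressures
#'   (mmHg); 0 makes the RHC columns equal the latent truth.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 127,
                          seed = 1L,
                          mpap_mean = 43.7, mpap_sd = 10.8,
                          pcwp_mean = 8.4, pcwp_sd = 3.8,
                          ci_mean = 1.85, ci_sd = 0.4,
                          ci_mpap_slope = -0.3,
                          ci_range = c(1.2, 4.0),
                          bsa_mean = 1.72, bsa_sd = 0.2,
                          spap_over_mpap = 1.81, spap_noise_sd = 4,
                          lvidd_base_mm = 41.5, lvidd_pvr_slope = -3.5,
                          lvidd_noise_sd = 3.8,
                          tvi_base_cm = 9.9, tvi_pvr_slope = -2.0,
                          tvi_noise_sd = 1.5,
                          velocity_noise_sd = 0.15,
                          rap_shift = 1.2, rap_noise_scale = 0.8,
                          rap_cutpoints = c(0.5, 2.0),
                          pvr_ref_mean = 987.2, pvr_ref_sd = 483.1,
                          p_tr_obtainable = 0.89,
                          p_pr_obtainable = 0.583,
                          pea_pvr_reduction_mean = 0.48,
                          pea_pvr_reduction_sd = 0.15,
                          pea_tpg_share = 0.9,
                          rhc_noise_sd = 0) {
  cfg <- as.list(environment())
  sds <- c(cfg$mpap_sd, cfg$pcwp_sd, cfg$ci_sd, cfg$bsa_sd, cfg$spap_noise_sd,
           cfg$lvidd_noise_sd, cfg$tvi_noise_sd, cfg$velocity_noise_sd,
           cfg$rap_noise_scale, cfg$pea_pvr_reduction_sd, cfg$rhc_noise_sd)
  if (any(sds < 0)) abort_config("all noise SDs must be non-negative")
  probs <- c(cfg$p_tr_obtainable, cfg$p_pr_obtainable)
  if (any(probs < 0 | probs > 1)) {
    abort_config("obtainability probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 1) abort_config("n_patients must be at least 1")
  if (cfg$seed < 0 || cfg$seed >= 2^31) {
    abort_config("seed must be a non-negative 32-bit integer")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Independent per-stage seeds derived from the master seed, so adding a
# stage never reshuffles an earlier one.
stage_seed <- function(config, stage) {
  stages <- c("truths", "echo", "missingness", "pea", "repeats")
  i <- match(stage, stages)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  sample.int(2147483646L, length(stages))[i]
}

# Echocardiographic state consistent with a given true hemodynamic state,
# via the inverse Bernoulli relation.  Must be called inside a seeded
# RNG context.
gen_echo_state <- function(mpap, spap, pvr, cfg) {
  n <- length(mpap)
  z_pvr <- (pvr - cfg$pvr_ref_mean) / cfg$pvr_ref_sd
  # ordinal RAP category: latent severity score with logistic noise
  latent <- cfg$rap_shift * z_pvr +
    if (cfg$rap_noise_scale > 0) rlogis(n, 0, cfg$rap_noise_scale) else 0
  rap <- ifelse(latent < cfg$rap_cutpoints[1], 3,
         ifelse(latent < cfg$rap_cutpoints[2], 8, 15))
  # IVC back-filled inside the region that maps to the drawn category
  u1 <- runif(n); u2 <- runif(n)
  ivc_d <- ifelse(rap == 3, 1.5 + 0.5 * u1,
           ifelse(rap == 8, 2.2 + 0.5 * u1, 2.3 + 0.6 * u1))
  ivc_c <- ifelse(rap == 15, 0.05 + 0.4 * u2, 0.55 + 0.35 * u2)
  trv <- sqrt(pmax(spap - rap, 1) / 4) +
    rnorm(n, 0, cfg$velocity_noise_sd)
  prv <- sqrt(pmax(mpap - rap, 0.5) / 4) +
    rnorm(n, 0, cfg$velocity_noise_sd)
  lvidd <- cfg$lvidd_base_mm + cfg$lvidd_pvr_slope * z_pvr +
    rnorm(n, 0, cfg$lvidd_noise_sd)
  tvi <- cfg$tvi_base_cm + cfg$tvi_pvr_slope * z_pvr +
    rnorm(n, 0, cfg$tvi_noise_sd)
  list(rap = rap, ivc_d = ivc_d, ivc_c = ivc_c,
       trv = pmin(pmax(trv, 0.3), 6.95),
       prv = pmin(pmax(prv, 0.3), 6.95),
       lvidd = pmin(pmax(lvidd, 21), 79),
       tvi = pmax(tvi, 2.5))
}

#' Generate a synthetic CTEPH baseline cohort
#'
#' Draws one pre-treatment record per patient.  Per patient: mPAP is drawn
#' from a truncated normal respecting the diagnostic floor (>= 25 mmHg),
#' PCWP from `[1, 15]` mmHg; cardiac index falls with severity; CO = CI x
#' BSA; TPG = mPAP - PCWP; true PVR = TPG/CO x 80.  sPAP tracks
#' `spap_over_mpap` x mPAP.  The RAP category shifts toward 8/15 mmHg at
#' higher PVR and the IVC measurements are back-filled consistently with
#' the drawn category, so the IVC-based RAP estimate always recovers it.
#' TRV and PRV follow the inverse Bernoulli construction
#' (`sqrt((pressure - RAP)/4)`) plus measurement noise; LVIDd and
#' TVI_RVOT fall linearly in standardized PVR (LV underfilling).
#' Deterministic given `config$seed`; every emitted record satisfies the
#' cohort invariants.
#'
#' @param config A [cohort_config()].
#' @return A data.frame in the cohort CSV dialect, with additional latent
#'   `true_*` columns (`true_mpap`, `true_spap`, `true_rap`, `true_pcwp`,
#'   `true_ci`, `true_co`, `true_tpg`, `true_pvr`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("config must be created by cohort_config()")
  }
  cfg <- config
  n <- cfg$n_patients

  set.seed(stage_seed(cfg, "truths"))
  loc <- trunc_location_for_mean(cfg$mpap_mean, cfg$mpap_sd, 25)
  mpap <- rnorm_trunc(n, loc, cfg$mpap_sd, lower = 25)
  pcwp <- rnorm_trunc(n, cfg$pcwp_mean, cfg$pcwp_sd, lower = 1, upper = 15)
  z_mpap <- (mpap - cfg$mpap_mean) / cfg$mpap_sd
  ci <- cfg$ci_mean + cfg$ci_mpap_slope * z_mpap +
    (if (cfg$ci_sd > 0) rnorm(n, 0, cfg$ci_sd) else 0)
  ci <- pmin(pmax(ci, cfg$ci_range[1]), cfg$ci_range[2])
  bsa <- rnorm_trunc(n, cfg$bsa_mean, cfg$bsa_sd, lower = 1.2)
  co <- ci * bsa
  tpg <- mpap - pcwp
  pvr <- 80 * tpg / co
  spap <- pmax(cfg$spap_over_mpap * mpap +
                 (if (cfg$spap_noise_sd > 0) rnorm(n, 0, cfg$spap_noise_sd) else 0),
               mpap + 5)

  set.seed(stage_seed(cfg, "echo"))
  echo <- gen_echo_state(mpap, spap, pvr, cfg)
  eps <- function() if (cfg$rhc_noise_sd > 0) rnorm(n, 0, cfg$rhc_noise_sd) else 0
  mpap_rhc <- mpap + eps()
  spap_rhc <- pmax(spap + eps(), mpap_rhc)

  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    timepoint = "pre",
    trv_ms = echo$trv,
    prv_ms = echo$prv,
    tvi_rvot_cm = echo$tvi,
    lvidd_mm = echo$lvidd,
    ivc_diam_cm = echo$ivc_d,
    ivc_collapse = echo$ivc_c,
    spap_rhc = spap_rhc,
    mpap_rhc = mpap_rhc,
    rap_rhc = echo$rap,
    pcwp = pcwp,
    co_lmin = co,
    bsa_m2 = bsa,
    true_mpap = mpap,
    true_spap = spap,
    true_rap = echo$rap,
    true_pcwp = pcwp,
    true_ci = ci,
    true_co = co,
    true_tpg = tpg,
    true_pvr = pvr,
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
  df
}

#' Apply Doppler-signal missingness to a cohort
#'
#' Each patient's TRV is set missing with probability
#' `1 - p_tr_obtainable` and PRV with probability `1 - p_pr_obtainable`,
#' independently (no measurable regurgitant jet).  Seeded from the
#' config's missingness sub-stream.
#'
#' @param cohort A cohort data.frame.
#' @param config A [cohort_config()].
#' @return The cohort with `trv_ms`/`prv_ms` entries set `NA`.
#' @export
apply_missingness <- function(cohort, config) {
  set.seed(stage_seed(config, "missingness"))
  n <- nrow(cohort)
  drop_tr <- runif(n) > config$p_tr_obtainable
  drop_pr <- runif(n) > config$p_pr_obtainable
  cohort$trv_ms[drop_tr] <- NA_real_
  cohort$prv_ms[drop_pr] <- NA_real_
  cohort
}

#' Generate paired pre/post-endarterectomy records
#'
#' For each baseline patient a fractional PVR reduction `r` is drawn
#' (truncated to `[0.05, 0.9]`) and the post-operative true state is
#' re-derived so the resistance identity holds exactly:
#' post PVR = pre PVR x (1 - r), with the fall split between the pressure
#' side (post TPG = pre TPG x (1-r)^`pea_tpg_share`) and the flow side
#' (post CO rises by (1-r)^(`pea_tpg_share` - 1)).  LVIDd recovers and
#' TVI_RVOT rises through the same standardized-PVR couplings (the
#' underfilling reverses), and all echo measurements are regenerated from
#' the new true state.
#'
#' @param cohort A baseline cohort from [generate_cohort()] (the latent
#'   `true_*` columns are required).
#' @param config A [cohort_config()].
#' @return A data.frame with two rows per patient (`timepoint` `pre` and
#'   `post`), ordered by patient.
#' @export
generate_pea_pairs <- function(cohort, config) {
  cfg <- config
  need <- c("true_mpap", "true_pcwp", "true_co", "true_tpg", "true_pvr")
  if (!all(need %in% names(cohort))) {
    abort_invalid("baseline cohort lacks the latent true_* columns")
  }
  n <- nrow(cohort)
  set.seed(stage_seed(cfg, "pea"))
  r <- rnorm_trunc(n, cfg$pea_pvr_reduction_mean, cfg$pea_pvr_reduction_sd,
                   lower = 0.05, upper = 0.9)
  keep <- 1 - r
  tpg_post <- cohort$true_tpg * keep^cfg$pea_tpg_share
  co_post <- cohort$true_co * keep^(cfg$pea_tpg_share - 1)
  pvr_post <- cohort$true_pvr * keep
  pcwp_post <- cohort$true_pcwp
  mpap_post <- pcwp_post + tpg_post
  spap_post <- pmax(cfg$spap_over_mpap * mpap_post +
                      (if (cfg$spap_noise_sd > 0) rnorm(n, 0, cfg$spap_noise_sd) else 0),
                    mpap_post + 2)
  echo <- gen_echo_state(mpap_post, spap_post, pvr_post, cfg)
  eps <- function() if (cfg$rhc_noise_sd > 0) rnorm(n, 0, cfg$rhc_noise_sd) else 0
  mpap_rhc <- mpap_post + eps()
  spap_rhc <- pmax(spap_post + eps(), mpap_rhc)

  post <- data.frame(
    patient_id = cohort$patient_id,
    timepoint = "post",
    trv_ms = echo$trv,
    prv_ms = echo$prv,
    tvi_rvot_cm = echo$tvi,
    lvidd_mm = echo$lvidd,
    ivc_diam_cm = echo$ivc_d,
    ivc_collapse = echo$ivc_c,
    spap_rhc = spap_rhc,
    mpap_rhc = mpap_rhc,
    rap_rhc = echo$rap,
    pcwp = pcwp_post,
    co_lmin = co_post,
    bsa_m2 = cohort$bsa_m2,
    true_mpap = mpap_post,
    true_spap = spap_post,
    true_rap = echo$rap,
    true_pcwp = pcwp_post,
    true_ci = co_post / cohort$bsa_m2,
    true_co = co_post,
    true_tpg = tpg_post,
    true_pvr = pvr_post,
    stringsAsFactors = FALSE
  )
  pre <- cohort[, names(post)]
  out <- rbind(pre, post)
  out <- out[order(out$patient_id, factor(out$timepoint, c("pre", "post"))), ]
  rownames(out) <- NULL
  validate_cohort(out)
  out
}

#' Generate duplicate measurements for reproducibility analysis
#'
#' Draws a reproducibility subset and adds independent observer
#' measurement error to each selected measurement twice, yielding
#' `<measure>_obs1`/`<measure>_obs2` columns suitable for
#' [run_reliability()].
#'
#' @param cohort A cohort data.frame.
#' @param config A [cohort_config()].
#' @param measures Named numeric vector: measurement column -> observer
#'   error SD (defaults mirror the poorer reproducibility of TVI_RVOT
#'   relative to LVIDd).
#' @param n_subjects Subset size (default 30).
#' @return A data.frame with `patient_id` and two observation columns per
#'   measure.
#' @export
generate_repeats <- function(cohort, config,
                             measures = c(tvi_rvot_cm = 1.2, lvidd_mm = 0.7),
                             n_subjects = 30) {
  set.seed(stage_seed(config, "repeats"))
  n_subjects <- min(n_subjects, nrow(cohort))
  idx <- sample.int(nrow(cohort), n_subjects)
  out <- data.frame(patient_id = cohort$patient_id[idx],
                    stringsAsFactors = FALSE)
  for (m in names(measures)) {
    truth <- cohort[[m]][idx]
    out[[paste0(m, "_obs1")]] <- truth + rnorm(n_subjects, 0, measures[[m]])
    out[[paste0(m, "_obs2")]] <- truth + rnorm(n_subjects, 0, measures[[m]])
  }
  out
}
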
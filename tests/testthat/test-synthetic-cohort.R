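test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 80, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(apply_missingness(a, cfg), apply_missingness(b, cfg))
  expect_identical(generate_pea_pairs(a, cfg), generate_pea_pairs(b, cfg))
})

test_that("baseline cohort reproduces the configured moments", {
  cfg <- cohort_config(n_patients = 1000, seed = 42)
  coh <- generate_cohort(cfg)
  expect_equal(mean(coh$mpap_rhc), 43.7, tolerance = 1 / 43.7)
  expect_lt(abs(mean(coh$true_pvr > 1000) - 0.409), 0.08)
  expect_equal(mean(coh$lvidd_mm), 41.5, tolerance = 0.6 / 41.5)
  expect_equal(sd(coh$lvidd_mm), 5.2, tolerance = 0.12)
  expect_equal(mean(coh$true_pvr), 987.2, tolerance = 0.08)
})

test_that("every emitted record satisfies the cohort invariants", {
  for (s in c(1, 9, 77)) {
    cfg <- cohort_config(n_patients = 300, seed = s)
    coh <- generate_cohort(cfg)
    expect_no_error(validate_cohort(coh))
    expect_true(all(coh$trv_ms > 0 & coh$trv_ms < 7))
    expect_true(all(coh$mpap_rhc >= 25 & coh$pcwp <= 15 & coh$pcwp >= 1))
    expect_true(all(coh$mpap_rhc <= coh$spap_rhc))
    expect_true(all(coh$rap_rhc %in% c(3, 8, 15)))
    # IVC back-fill always recovers the drawn RAP category
    expect_equal(estimate_rap_from_ivc(coh$ivc_diam_cm, coh$ivc_collapse),
                 coh$true_rap)
    expect_no_error(validate_cohort(generate_pea_pairs(coh, cfg)))
  }
})

test_that("noise-free generation makes derive_indices an exact inverse", {
  cfg <- cohort_config(n_patients = 400, seed = 7, velocity_noise_sd = 0)
  d <- derive_indices(generate_cohort(cfg))
  expect_equal(d$spap_echo, d$true_spap, tolerance = 1e-12)
  expect_equal(d$mpap_echo, d$true_mpap, tolerance = 1e-12)
  expect_equal(d$pvr, d$true_pvr, tolerance = 1e-12)
  expect_equal(d$rap_echo, d$true_rap)
})

test_that("LV underfilling couples LVIDd negatively to PVR", {
  for (s in 1:4) {
    coh <- generate_cohort(cohort_config(n_patients = 500, seed = s))
    expect_lt(spearman_rho(coh$lvidd_mm, coh$true_pvr)$rho, 0)
    d <- suppressWarnings(derive_indices(coh))
    expect_gt(spearman_rho(d$spap_lvidd, d$true_pvr)$rho, 0)
  }
})

test_that("missingness removes signals at the configured rates", {
  cfg <- cohort_config(n_patients = 200, seed = 5,
                       p_tr_obtainable = 1, p_pr_obtainable = 1)
  coh <- generate_cohort(cfg)
  expect_identical(apply_missingness(coh, cfg), coh)

  cfg0 <- cohort_config(n_patients = 200, seed = 5, p_tr_obtainable = 0)
  m0 <- apply_missingness(coh, cfg0)
  expect_true(all(is.na(m0$trv_ms)))
  d0 <- derive_indices(m0)
  expect_true(all(is.na(d0$spap_echo) & is.na(d0$spap_lvidd) &
                    is.na(d0$abbas_index)))

  cfg1 <- cohort_config(n_patients = 10000, seed = 11)
  m1 <- apply_missingness(generate_cohort(cfg1), cfg1)
  expect_lt(abs(mean(!is.na(m1$trv_ms)) - 0.89), 0.015)
  expect_lt(abs(mean(!is.na(m1$prv_ms)) - 0.583), 0.015)
})

test_that("endarterectomy pairs honour the PVR reduction model", {
  cfg <- cohort_config(n_patients = 150, seed = 3,
                       pea_pvr_reduction_mean = 0.5, pea_pvr_reduction_sd = 0,
                       velocity_noise_sd = 0, spap_noise_sd = 0)
  coh <- generate_cohort(cfg)
  pp <- generate_pea_pairs(coh, cfg)
  expect_equal(nrow(pp), 2 * nrow(coh))
  pre <- pp[pp$timepoint == "pre", ]
  post <- pp[pp$timepoint == "post", ]
  expect_equal(post$true_pvr, pre$true_pvr * 0.5, tolerance = 1e-12)

  cfg2 <- cohort_config(n_patients = 1000, seed = 21)
  pp2 <- generate_pea_pairs(generate_cohort(cfg2), cfg2)
  pre2 <- pp2[pp2$timepoint == "pre", ]
  post2 <- pp2[pp2$timepoint == "post", ]
  ratio <- post2$true_pvr / pre2$true_pvr
  expect_lt(abs(mean(ratio) - 0.52), 0.05)
  # underfilling reverses: LVIDd recovers and CO rises after surgery
  expect_gt(mean(post2$lvidd_mm - pre2$lvidd_mm), 0)
  expect_true(all(post2$co_lmin > pre2$co_lmin))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), class = "echopvr_config_error")
  expect_error(cohort_config(p_tr_obtainable = 1.2), class = "echopvr_config_error")
  expect_error(cohort_config(mpap_sd = -1), class = "echopvr_config_error")
  expect_error(generate_cohort(list(n_patients = 5)), class = "echopvr_config_error")
})
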
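test_that("IVC size/collapse maps to the three RAP categories", {
  expect_equal(estimate_rap_from_ivc(1.8, 0.6), 3)
  expect_equal(estimate_rap_from_ivc(2.5, 0.2), 15)
  expect_equal(estimate_rap_from_ivc(2.5, 0.6), 8)
  expect_equal(estimate_rap_from_ivc(1.8, 0.2), 8)  # discordant the other way

  # total over an exhaustive grid, image exactly {3, 8, 15}
  grid <- expand.grid(d = seq(0.5, 4, by = 0.1), c = seq(0, 1, by = 0.05))
  rap <- estimate_rap_from_ivc(grid$d, grid$c)
  expect_false(anyNA(rap))
  expect_setequal(unique(rap), c(3, 8, 15))

  expect_error(estimate_rap_from_ivc(-1, 0.5), class = "echopvr_invalid_measurement")
  expect_error(estimate_rap_from_ivc(2, 1.2), class = "echopvr_invalid_measurement")
  expect_true(is.na(estimate_rap_from_ivc(NA, 0.5)))
})

test_that("Bernoulli pressure estimates follow 4 v^2 + RAP", {
  expect_equal(spap_echo(4.2, 3), 73.56)
  expect_equal(spap_echo(1.0, 3), 7.0)
  expect_equal(spap_echo(3.0, 15), 51.0)
  expect_equal(mpap_echo(2.8, 3), 34.36)
  expect_equal(mpap_echo(1.0, 8), 12.0)
  expect_equal(mpap_echo(2.0, 3), 19.0)

  # strictly increasing in velocity; zero-velocity limit is RAP itself
  v <- seq(0.5, 6, by = 0.25)
  expect_true(all(diff(spap_echo(v, 8)) > 0))
  expect_equal(4 * 0^2 + 8, 8)

  # missing velocity propagates, never errors
  expect_true(is.na(spap_echo(NA, 3)))
  expect_true(is.na(mpap_echo(NA, 15)))
  expect_error(spap_echo(-1, 3), class = "echopvr_invalid_measurement")
  expect_error(spap_echo(3, 5), class = "echopvr_invalid_measurement")
})

test_that("pressure/LVIDd index is a homogeneous ratio", {
  expect_equal(pressure_lvidd_index(80, 40), 2.0)
  expect_equal(pressure_lvidd_index(spap_echo(4.2, 3), 41.5), 73.56 / 41.5)
  expect_equal(pressure_lvidd_index(mpap_echo(2.8, 3), 41.5), 34.36 / 41.5)
  for (k in c(0.5, 2, 7)) {
    expect_equal(pressure_lvidd_index(80 * k, 40), k * 2)
    expect_equal(pressure_lvidd_index(80, 40 * k), 2 / k)
  }
  expect_error(pressure_lvidd_index(80, 0), class = "echopvr_invalid_measurement")
})

test_that("TRV^2/TVI_RVOT comparator index", {
  expect_equal(abbas_index(4.2, 9.9), 17.64 / 9.9)
  expect_equal(abbas_index(1, 1), 1)
  expect_equal(abbas_index(3, 12), 0.75)
  expect_true(is.na(abbas_index(NA, 9.9)))
  expect_true(is.na(abbas_index(4.2, NA)))
})

test_that("TPG subtracts wedge from mean PAP, warning when non-positive", {
  expect_equal(transpulmonary_gradient(43.7, 8.4), 35.3)
  expect_equal(transpulmonary_gradient(25, 15), 10)
  expect_warning(tpg0 <- transpulmonary_gradient(30, 30), "implausible")
  expect_equal(tpg0, 0)
})

test_that("PVR conversion and round-trip", {
  expect_equal(pvr_dyn(35, 3.5), 800)
  expect_equal(pvr_dyn(12.5, 1.0), 1000)
  expect_equal(pvr_dyn(0, 5), 0)
  expect_equal(pvr_wood(35, 3.5), 10)
  # round-trip recovers TPG to machine precision
  set.seed(1)
  tpg <- runif(50, 5, 60); co <- runif(50, 1, 8)
  expect_equal(pvr_dyn(tpg, co) * co / 80, tpg, tolerance = 1e-12)
  expect_error(pvr_dyn(10, 0), class = "echopvr_invalid_measurement")
})

test_that("cardiac output from index and BSA", {
  expect_equal(cardiac_output(2.2, 1.72), 3.784)
  expect_equal(cardiac_output(1, 1), 1)
  expect_equal(cardiac_output(3, 2), 6)
  expect_error(cardiac_output(-1, 1.7), class = "echopvr_invalid_measurement")
})

test_that("cutoff classification is inclusive at the boundary", {
  expect_true(classify_high_pvr(1.94, 1.94))
  expect_false(classify_high_pvr(1.93, 1.94))
  expect_true(classify_high_pvr(0.97, 0.97))
  set.seed(2)
  v <- runif(100, 0, 3); cut <- runif(100, 0, 3)
  below <- v < cut
  expect_equal(classify_high_pvr(v, cut), !below)
})

test_that("reduction rate is the relative decrease in percent", {
  expect_equal(reduction_rate(2.04, 0.97), 100 * (2.04 - 0.97) / 2.04)
  expect_equal(reduction_rate(100, 100), 0)
  expect_equal(reduction_rate(930.9, 486.4), 100 * (930.9 - 486.4) / 930.9)
  expect_error(reduction_rate(0, 1), class = "echopvr_invalid_measurement")
})

make_echo <- function(trv = 4.2, prv = 2.8, tvi = 9.9) {
  list(patient_id = "P1", timepoint = "pre", trv = trv, prv = prv,
       tvi_rvot = tvi, lvidd = 41.5, ivc_diameter = 1.8, ivc_collapse = 0.6)
}
make_rhc <- function() {
  list(patient_id = "P1", timepoint = "pre", spap_rhc = 79, mpap_rhc = 43.7,
       rap_rhc = 3, pcwp = 8.4, co = 3.784, bsa = 1.72)
}

test_that("derive_all composes the elementary operations", {
  d <- derive_all(make_echo(), make_rhc())
  expect_equal(d$rap_echo, 3)
  expect_equal(d$spap_echo, 73.56)
  expect_equal(d$mpap_echo, 34.36)
  expect_equal(d$spap_lvidd, 73.56 / 41.5)
  expect_equal(d$mpap_lvidd, 34.36 / 41.5)
  expect_equal(d$abbas_index, 17.64 / 9.9)
  expect_equal(d$tpg, 35.3)
  expect_equal(d$pvr, 35.3 / 3.784 * 80)
  expect_equal(d$pvr_wood, 35.3 / 3.784)
  expect_false(d$high_pvr)
})

test_that("derive_all propagates missing velocities to exactly the dependents", {
  d <- derive_all(make_echo(trv = NA), make_rhc())
  expect_true(is.na(d$spap_echo) && is.na(d$spap_lvidd) && is.na(d$abbas_index))
  expect_false(is.na(d$mpap_echo) || is.na(d$mpap_lvidd))

  d <- derive_all(make_echo(prv = NA), make_rhc())
  expect_true(is.na(d$mpap_echo) && is.na(d$mpap_lvidd))
  expect_false(is.na(d$spap_echo) || is.na(d$spap_lvidd) || is.na(d$abbas_index))

  # never raises on missing optionals
  expect_no_error(derive_all(make_echo(trv = NA, prv = NA, tvi = NA), make_rhc()))
})

test_that("derive_all enforces pairing and flags severe TR", {
  rhc <- make_rhc(); rhc$patient_id <- "P2"
  expect_error(derive_all(make_echo(), rhc), class = "echopvr_pairing_error")
  expect_warning(derive_all(make_echo(trv = 6.4), make_rhc()), "severe-TR")
})
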
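test_that("mass conversion applies the 1.03 kg/L density", {
  expect_equal(mass_from_volume(1000), 1.03)
  expect_equal(mass_from_volume(1829), 1.88387)
  expect_equal(mass_from_volume(0), 0)
  expect_error(mass_from_volume(-1), "non-negative")
})

test_that("dose model reproduces analytic values", {
  expect_equal(dose_from_activity(5, 0, 1829), 250 / 1.88387)
  expect_equal(dose_from_activity(0, 0.3, 500), 0)
  expect_equal(dose_from_activity(1, 0.5, 1000 / 1.03), 25)
  expect_error(dose_from_activity(1, 1, 1000), "shunt")
  expect_error(dose_from_activity(1, 0, 0), "positive")
})

test_that("activity planning inverts the dose model", {
  expect_equal(activity_for_dose(25, 0.5, 1000 / 1.03), 1)
  set.seed(5)
  for (i in 1:50) {
    a <- runif(1, 0.1, 10); s <- runif(1, 0, 0.6); v <- runif(1, 100, 3000)
    expect_equal(activity_for_dose(dose_from_activity(a, s, v), s, v), a,
                 tolerance = 1e-12)
    expect_equal(dose_from_activity(activity_for_dose(a * 30, s, v), s, v),
                 a * 30, tolerance = 1e-12)
  }
})

test_that("dose is linear in activity and decreasing in shunt and volume", {
  base <- dose_from_activity(2, 0.1, 1500)
  expect_equal(dose_from_activity(4, 0.1, 1500), 2 * base)
  expect_lt(dose_from_activity(2, 0.3, 1500), base)
  expect_lt(dose_from_activity(2, 0.1, 2000), base)
})

test_that("lung shunt fraction follows the standard count definition", {
  liver <- compartment("liver", 1829, 900)
  expect_equal(lung_shunt_fraction(compartment("lungs", 4000, 0), liver), 0)
  expect_equal(lung_shunt_fraction(compartment("lungs", 4000, 900), liver), 0.5)
  expect_equal(lung_shunt_fraction(compartment("lungs", 4000, 10),
                                   compartment("liver", 1829, 90)), 0.10)
  expect_error(lung_shunt_fraction(compartment("lungs", 4000, 0),
                                   compartment("liver", 1829, 0)), "counts")
})

test_that("partition subtracts compartments and bounds the uptake fraction", {
  p <- partition(compartment("liver", 1829, 1000),
                 compartment("tumor", 610, 691))
  expect_equal(p$tumor_uptake_fraction, 0.691)
  expect_equal(p$healthy_liver$volume_mL, 1219)
  expect_equal(p$healthy_liver$counts, 309)
  p0 <- partition(compartment("liver", 1829, 1000),
                  compartment("tumor", 610, 0))
  expect_equal(p0$tumor_uptake_fraction, 0)
  expect_equal(p0$healthy_liver$counts, 1000)
  pall <- partition(compartment("liver", 1829, 1000),
                    compartment("tumor", 1829, 1000))
  expect_equal(pall$tumor_uptake_fraction, 1)
  expect_equal(pall$healthy_liver$counts, 0)
  expect_error(partition(compartment("liver", 1829, 1000),
                         compartment("tumor", 2000, 10)), "volume")
  expect_error(partition(compartment("liver", 1829, 1000),
                         compartment("tumor", 610, 1100)), "counts")
})

test_that("dose report splits activity by counts and conserves it", {
  rep <- dose_report(dose_plan(5, 0), compartment("liver", 1829, 1000),
                     compartment("tumor", 610, 691))
  expect_equal(rep$A_tum_GBq, 3.455)
  expect_equal(rep$A_HL_GBq, 1.545)
  expect_equal(rep$A_tum_GBq + rep$A_HL_GBq, 5 * (1 - 0))
  expect_equal(rep$D_tum_Gy, 50 * 3.455 / mass_from_volume(610))
  expect_equal(rep$D_HL_Gy, 50 * 1.545 / mass_from_volume(1219))
  # treated-volume dose lies between the compartment doses
  expect_true(min(rep$D_tum_Gy, rep$D_HL_Gy) <= rep$D_treated_Gy)
  expect_true(rep$D_treated_Gy <= max(rep$D_tum_Gy, rep$D_HL_Gy))
})

test_that("uniform uptake gives equal tumor, healthy and treated doses", {
  liver <- compartment("liver", 1500, 3000)
  tumor <- compartment("tumor", 300, 600)  # counts proportional to volume
  rep <- dose_report(dose_plan(2, 0.1), liver, tumor)
  expect_equal(rep$D_tum_Gy, rep$D_HL_Gy)
  expect_equal(rep$D_tum_Gy, rep$D_treated_Gy)
})

test_that("raising the shunt strictly lowers every hepatic dose", {
  liver <- compartment("liver", 1829, 1000)
  tumor <- compartment("tumor", 610, 691)
  r1 <- dose_report(dose_plan(5, 0.05), liver, tumor)
  r2 <- dose_report(dose_plan(5, 0.25), liver, tumor)
  expect_lt(r2$D_treated_Gy, r1$D_treated_Gy)
  expect_lt(r2$D_tum_Gy, r1$D_tum_Gy)
  expect_lt(r2$D_HL_Gy, r1$D_HL_Gy)
})

test_that("dose report JSON round-trips its numbers", {
  rep <- dose_report(dose_plan(5, 0), compartment("liver", 1829, 1000),
                     compartment("tumor", 610, 691))
  parsed <- jsonlite::fromJSON(dose_report_json(rep))
  expect_equal(parsed$D_treated_Gy, rep$D_treated_Gy)
  expect_equal(parsed$tumor_uptake_fraction, 0.691)
})
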
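test_that("total blood volume matches hand-evaluated Nadler forms", {
  # cubic dialect: 0.3669*1.8^3 + 0.03219*80 + 0.6041
  expect_equal(compute_tbv(1.8, 80, "male"), 5.319, tolerance = 1e-3)
  # height-linear dialect, same coefficients
  expect_equal(compute_tbv(1.8, 80, "male", dialect = "as_printed"),
               3.840, tolerance = 1e-3)
  # female linear intercept at vanishing height/weight
  expect_equal(compute_tbv(1e-12, 1e-12, "female", dialect = "as_printed"),
               0.1833, tolerance = 1e-6)
  expect_error(compute_tbv(-1.8, 80, "male"), "height",
               class = "neuropk_invalid_input")
  expect_error(compute_tbv(1.8, 0, "male"), "weight",
               class = "neuropk_invalid_input")
})

test_that("adult GFR follows the printed coefficient table", {
  # Caucasian male at reference creatinine: 141 * 0.993^45
  expect_equal(compute_gfr(subject_preset("adult_male")),
               141 * 0.993^45, tolerance = 1e-12)
  expect_equal(compute_gfr(subject_preset("adult_male")), 102.8,
               tolerance = 1e-3)
  # African-American female at reference creatinine: 166 * 0.993^45
  f_aa <- subject_profile("adult", "female", "african_american")
  expect_equal(compute_gfr(f_aa), 166 * 0.993^45, tolerance = 1e-12)
  expect_equal(compute_gfr(f_aa), 121.0, tolerance = 1e-3)
  # kidney failure zeroes the rate
  dead <- subject_profile("adult", "male", gfr_function = 0)
  expect_equal(compute_gfr(dead), 0)
  # elevated creatinine lowers GFR; reference creatinine leaves term inert
  high_cr <- subject_profile("adult", "male", serum_creatinine = 1.8)
  expect_lt(compute_gfr(high_cr), compute_gfr(subject_preset("adult_male")))
  # per-hour export applies the x60 conversion only
  expect_equal(compute_gfr(subject_preset("adult_male"), per_hour = TRUE),
               60 * compute_gfr(subject_preset("adult_male")))
  expect_error(compute_gfr(subject_preset("neonate")),
               class = "neuropk_unsupported")
})

test_that("GFR scales linearly in kidney-health fraction", {
  base <- compute_gfr(subject_profile("adult", "female", gfr_function = 1))
  for (f in c(0.25, 0.5, 0.8)) {
    p <- subject_profile("adult", "female", gfr_function = f)
    expect_equal(compute_gfr(p), f * base, tolerance = 1e-12)
  }
})

test_that("neonatal GFR is BSA-scaled from the 47 ml/min/1.73 m2 preset", {
  expect_equal(neonatal_gfr(1.73, 1), 47)
  expect_equal(neonatal_gfr(0.25, 1), 47 * 0.25 / 1.73, tolerance = 1e-12)
  expect_equal(neonatal_gfr(0.25, 1), 6.79, tolerance = 1e-3)
  expect_equal(neonatal_gfr(0.3, 0), 0)
  expect_error(neonatal_gfr(0, 1), class = "neuropk_invalid_input")
})

test_that("filtration coefficient matches the sieving curve and clamps", {
  # at MW = 27096 the exponent vanishes: -0.04094 + 1.19614/2
  expect_equal(filtration_coefficient(27096), 0.55713, tolerance = 1e-5)
  expect_equal(filtration_coefficient(10700), 0.872, tolerance = 1e-3)
  # asymptotes clamp into [0, 1]
  expect_equal(filtration_coefficient(1e9), 0)
  expect_equal(filtration_coefficient(1e-6), 1)
  expect_error(filtration_coefficient(-5), class = "neuropk_invalid_input")
})

test_that("filtration coefficient is non-increasing and bounded on a MW grid", {
  mw <- 10^seq(0, 6, length.out = 400)
  cf <- filtration_coefficient(mw)
  expect_true(all(cf >= 0 & cf <= 1))
  expect_true(all(diff(cf) <= 1e-12))
})

test_that("renal clearance and half-life compose as a first-order chain", {
  gfr <- compute_gfr(subject_preset("adult_male"))
  cl <- renal_clearance(gfr, filtration_coefficient(10700))
  expect_equal(cl, gfr * filtration_coefficient(10700))
  expect_equal(renal_clearance(gfr, 0), 0)
  expect_equal(renal_clearance(0, 0.5), 0)
  t12 <- elimination_half_life(cl, 6000)
  expect_equal(t12, log(2) * 6000 / cl, tolerance = 1e-12)
  expect_equal(t12, 46.4, tolerance = 0.01)
  # doubling clearance halves the half-life
  expect_equal(elimination_half_life(2 * cl, 6000), t12 / 2)
  # zero clearance is the explicit infinite sentinel
  expect_identical(elimination_half_life(0, 6000), Inf)
})

test_that("half-life is non-decreasing in molecular weight", {
  gfr <- compute_gfr(subject_preset("adult_male"))
  mw <- 10^seq(0, 6, length.out = 200)
  t12 <- vapply(mw, function(m) {
    elimination_half_life(
      max(renal_clearance(gfr, filtration_coefficient(m)), 1e-12), 6000)
  }, numeric(1))
  expect_true(all(diff(t12) >= -1e-9 * t12[-length(t12)]))
  # dimer outlives monomer at fixed GFR and volume
  t_mono <- elimination_half_life(
    renal_clearance(gfr, filtration_coefficient(10700)), 6000)
  t_dim <- elimination_half_life(
    renal_clearance(gfr, filtration_coefficient(21000)), 6000)
  expect_gt(t_dim, t_mono)
})

test_that("kidney failure scales half-life multiplicatively, not MW-dependently", {
  # the relative half-life increase under failing kidneys is constant in
  # MW (clearance is linear in gfr_function); the MW dependence of the
  # failure effect is in the absolute, not relative, increase
  gfr_full <- compute_gfr(subject_profile("adult", "male", gfr_function = 1))
  gfr_low <- compute_gfr(subject_profile("adult", "male", gfr_function = 0.1))
  mws <- c(10700, 21000, 26000, 46000)
  ratios <- vapply(mws, function(m) {
    cf <- filtration_coefficient(m)
    elimination_half_life(renal_clearance(gfr_low, cf), 6000) /
      elimination_half_life(renal_clearance(gfr_full, cf), 6000)
  }, numeric(1))
  expect_equal(ratios, rep(10, length(mws)), tolerance = 1e-9)
  abs_increase <- vapply(mws, function(m) {
    cf <- filtration_coefficient(m)
    elimination_half_life(renal_clearance(gfr_low, cf), 6000) -
      elimination_half_life(renal_clearance(gfr_full, cf), 6000)
  }, numeric(1))
  expect_true(all(diff(abs_increase) > 0))
})

test_that("subject presets carry the documented volumes", {
  n <- subject_preset("neonate")
  expect_equal(c(n$brain_volume, n$blood_volume), c(0.42, 0.28))
  m <- subject_preset("adult_male")
  expect_equal(c(m$brain_volume, m$blood_volume), c(1.42, 6.0))
  f <- subject_preset("adult_female")
  expect_equal(f$brain_volume, 1.05)
  expect_error(subject_profile("adult", "male", gfr_function = 1.5),
               class = "neuropk_invalid_input")
})

test_that("the shipped biomarker panel lists the four modeled markers", {
  panel <- biomarker_panel()
  expect_setequal(panel$name,
                  c("s100b_monomer", "s100b_dimer", "gfap", "uchl1"))
  g <- get_biomarker("gfap")
  expect_equal(g$molecular_weight, 26000)
  expect_equal(g$brain_conc, 1.0)
  u <- get_biomarker("uchl1")
  expect_equal(u$brain_conc, 7.6)
  expect_error(get_biomarker("tau"), class = "neuropk_invalid_input")
})
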
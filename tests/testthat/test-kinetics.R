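test_that("build_model resolves clearances by the volume-scaling rules", {
  cal <- shared_cal()
  adult <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal)
  # renal chain: GFR x C_F at 10.7 kD
  expect_equal(adult$renal$renal_clearance,
               compute_gfr(subject_preset("adult_male")) *
                 filtration_coefficient(10700), tolerance = 1e-12)
  expect_equal(adult$renal$renal_clearance, 89.7, tolerance = 0.01)
  # adult brain: reference clearance, 2.5% steady leak
  expect_equal(adult$organs$brain$max_transfer_clearance,
               cal$max_transfer_clearance)
  expect_equal(adult$organs$brain$leak_fraction, 2.5)
  # neonate brain clearance scales with brain volume (0.42/1.42), 10% leak
  neo <- build_model(subject_preset("neonate"),
                     get_biomarker("s100b_monomer"), cal)
  expect_equal(neo$organs$brain$max_transfer_clearance,
               cal$max_transfer_clearance * 0.42 / 1.42, tolerance = 1e-12)
  expect_equal(neo$organs$brain$leak_fraction, 10)
  # skin: 7.8 l, volume-scaled clearance, 2% leak
  skin <- build_model(subject_preset("light_skin"),
                      get_biomarker("s100b_monomer"), cal,
                      include_skin = TRUE)
  expect_equal(skin$organs$skin$volume, 7.8)
  expect_equal(skin$organs$skin$max_transfer_clearance,
               cal$max_transfer_clearance * 7.8 / 1.42, tolerance = 1e-12)
  expect_equal(skin$organs$skin$leak_fraction, 2)
  expect_equal(skin$organs$skin$tissue_conc, 0.288)
  # guard rails
  expect_error(build_model(subject_preset("neonate"),
                           get_biomarker("s100b_monomer"), cal,
                           include_skin = TRUE),
               class = "neuropk_unsupported")
  expect_error(build_model(subject_preset("adult_male"),
                           get_biomarker("s100b_monomer"), "nope"),
               class = "neuropk_configuration_error")
})

test_that("event-free runs rise monotonically to the analytic steady state", {
  cal <- shared_cal()
  model <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal)
  res <- simulate_serum(model, 1440)
  expect_true(all(diff(res$serum_conc) >= -1e-12))
  expect_equal(res$serum_conc[1], 0)
  target <- analytic_steady_state(model)
  expect_equal(res$serum_conc[length(res$serum_conc)], target,
               tolerance = 1e-3)
  ss <- detect_steady_state(res, rel_tol = 1e-4, window = 60)
  expect_false(is.null(ss))
  expect_equal(ss$conc, target, tolerance = 1e-3)
})

test_that("analytic steady state has the closed-form limits", {
  cal <- shared_cal()
  model <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal)
  # huge renal clearance washes serum to zero
  washed <- model
  washed$renal$renal_clearance <- 1e12
  expect_lt(analytic_steady_state(washed), 1e-10)
  # no elimination: serum equilibrates with the brain source
  closed <- model
  closed$renal$renal_clearance <- 0
  expect_equal(analytic_steady_state(closed),
               model$organs$brain$tissue_conc)
  # all clearances zero is undefined
  dead <- closed
  dead$organs$brain$max_transfer_clearance <- 0
  expect_error(analytic_steady_state(dead),
               class = "neuropk_invalid_input")
  # unidirectional variant: sum CL B / CL_renal
  uni <- build_model(subject_preset("adult_male"),
                     get_biomarker("s100b_monomer"), cal,
                     bidirectional = FALSE)
  cl_b <- 0.025 * cal$max_transfer_clearance
  expect_equal(analytic_steady_state(uni),
               cl_b * 10 / uni$renal$renal_clearance, tolerance = 1e-12)
})

test_that("ODE plateaus agree with the algebraic oracle on random models", {
  set.seed(421)
  cal <- shared_cal()
  for (i in 1:25) {
    model <- random_model(cal)
    target <- analytic_steady_state(model)
    dur <- 14 * system_time_constant(model)
    res <- simulate_serum(model, dur, dt = dur / 400)
    expect_equal(res$serum_conc[length(res$serum_conc)], target,
                 tolerance = 1e-3)
  }
})

test_that("mass is conserved with and without disruption events", {
  set.seed(77)
  cal <- shared_cal()
  for (i in 1:10) {
    model <- random_model(cal)
    dur <- 8 * system_time_constant(model)
    if (i %% 2 == 0) {
      model$events <- list(disruption_event(dur / 2, runif(1, 20, 100),
                                            runif(1, 3, 15)))
    }
    res <- simulate_serum(model, dur, dt = dur / 300)
    total_in <- res$influx_mass[length(res$times)]
    expect_lt(mass_balance(res), 1e-6 * abs(total_in))
  }
  # a zero-leak model has no dynamics at all
  quiet <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal)
  quiet$organs$brain$leak_fraction <- 0
  res <- simulate_serum(quiet, 200)
  expect_equal(max(res$serum_conc), 0)
  expect_equal(res$influx_mass[length(res$times)], 0)
  expect_equal(res$excreted_mass[length(res$times)], 0)
})

test_that("raising the brain source concentration raises the plateau", {
  cal <- shared_cal()
  subject <- subject_preset("adult_male")
  concs <- c(5, 10, 20, 40)  # gliosis proxy
  plateaus <- vapply(concs, function(b) {
    analytic_steady_state(build_model(
      subject, biomarker("s100b_like", 10700, b), cal))
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
})

test_that("post-event decay matches the first-order elimination chain", {
  cal <- shared_cal()
  subject <- subject_preset("adult_male")
  rates <- sapply(c(monomer = 10700, dimer = 21000), function(mw) {
    marker <- biomarker("m", mw, 10)
    ev <- disruption_event(600, 100, cal$recovery_tau)
    model <- build_model(subject, marker, cal, events = list(ev))
    res <- simulate_serum(model, 1800, dt = 0.5)
    plateau <- analytic_steady_state(build_model(subject, marker, cal))
    # fit the tail, several recovery constants after the event
    tail_sel <- res$times >= 700 & res$times <= 1200
    fitted <- fit_decay_rate(res$times[tail_sel], res$serum_conc[tail_sel],
                             plateau)
    cl_total <- model$renal$renal_clearance +
      0.025 * model$organs$brain$max_transfer_clearance
    expected <- log(2) / elimination_half_life(cl_total, 6000)
    expect_equal(fitted, expected, tolerance = 0.05)
    fitted
  })
  # the heavier dimer returns to baseline more slowly
  expect_lt(rates["dimer"], rates["monomer"])
})

test_that("steady-state detection handles degenerate series", {
  cal <- shared_cal()
  model <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal)
  fake <- function(conc) {
    structure(list(times = seq(0, 500, by = 1), serum_conc = conc,
                   influx_mass = conc, excreted_mass = conc,
                   index = rep(2.5, 501), model = model, dt = 1),
              class = "simulation_result")
  }
  # constant series settles as soon as a full window fits
  out <- detect_steady_state(fake(rep(3, 501)), rel_tol = 1e-4, window = 60)
  expect_equal(out$time, 60)
  expect_equal(out$conc, 3)
  # a linearly growing series never settles
  expect_null(detect_steady_state(fake(seq(0, 5, length.out = 501)),
                                  rel_tol = 1e-4, window = 60))
})

test_that("tidiers and autoplot expose the simulation as tabular data", {
  cal <- shared_cal()
  model <- build_model(subject_preset("adult_male"),
                       get_biomarker("s100b_monomer"), cal,
                       events = list(disruption_event(100, 100, 8)))
  res <- simulate_serum(model, 300)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time_min", "serum_ng_ml", "excreted_ng",
                     "influx_ng", "index"))
  expect_true(all(diff(td$excreted_ng) >= 0))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$mass_balance_ng, 1e-6 * max(td$influx_ng))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(tidy(shared_cal()), "tbl_df")
  expect_equal(glance(shared_cal())$recovery_tau_min,
               shared_cal()$recovery_tau)
})
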
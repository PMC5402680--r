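# Shared fixtures: one calibration per test session, random valid
# event-free models, and an exponential-decay fitter.

shared_cal <- function() default_calibration()

# A random valid event-free model spanning both age classes, a wide MW
# range, and optional skin.
random_model <- function(cal = shared_cal()) {
  adult <- runif(1) < 0.7
  bidir <- runif(1) < 0.8
  # unidirectional models eliminate through the kidney only, so keep MW
  # below the sieving cutoff (~74 kDa) where renal clearance vanishes
  max_log_mw <- if (bidir) 5.3 else 4.6
  subject <- if (adult) {
    subject_profile(
      "adult", sample(c("male", "female"), 1),
      brain_volume = runif(1, 0.8, 2.0),
      blood_volume = runif(1, 3, 8),
      gfr_function = runif(1, 0.2, 1),
      skin_marker_conc = runif(1, 0, 3)
    )
  } else {
    subject_profile(
      "neonate", "male",
      brain_volume = runif(1, 0.2, 0.7),
      blood_volume = runif(1, 0.15, 0.5),
      body_surface_area = runif(1, 0.15, 0.4),
      gfr_function = runif(1, 0.2, 1)
    )
  }
  marker <- biomarker("random",
                      molecular_weight = 10^runif(1, 3.2, max_log_mw),
                      brain_conc = runif(1, 0.5, 20))
  build_model(subject, marker, cal,
              include_skin = adult && runif(1) < 0.5,
              bidirectional = bidir)
}

# Total steady clearance + system time constant for sizing simulations.
system_time_constant <- function(model) {
  cls <- sum(vapply(model$organs,
                    function(o) o$leak_fraction / 100 * o$max_transfer_clearance,
                    numeric(1)))
  total <- model$renal$renal_clearance +
    if (model$bidirectional) cls else 0
  model$subject$blood_volume * 1000 / total
}

# Least-squares single-exponential decay rate of (conc - plateau) over a
# post-event tail.
fit_decay_rate <- function(times, conc, plateau) {
  y <- conc - plateau
  keep <- y > 1e-6 * max(y)
  fit <- stats::lm(log(y[keep]) ~ times[keep])
  -unname(coef(fit)[2])
}
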
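# Scripted experiments: age contrast, skin pigmentation, sex contrast,
# kidney-failure half-life sweep. All deterministic.

.neuropk_cache <- new.env(parent = emptyenv())

#' Default BBB calibration (memoised)
#'
#' Runs [calibrate_bbb()] with adult-male S100B-monomer defaults once per
#' session and caches the result; every scenario shares this single
#' calibrated constant.
#'
#' @return A `bbb_calibration`.
#' @export
default_calibration <- function() {
  if (is.null(.neuropk_cache$calibration)) {
    .neuropk_cache$calibration <- calibrate_bbb()
  }
  .neuropk_cache$calibration
}

# Resolved-parameter echo for auditability: every scenario arm records the
# full parameter set it ran with.
model_echo <- function(model) {
  organs <- lapply(model$organs, function(o) {
    list(volume_l = o$volume, tissue_conc_ng_ml = o$tissue_conc,
         max_transfer_clearance_ml_min = o$max_transfer_clearance,
         leak_fraction_pct = o$leak_fraction)
  })
  list(
    subject = unclass(model$subject),
    biomarker = list(name = model$biomarker$name,
                     molecular_weight_da = model$biomarker$molecular_weight,
                     brain_conc_ng_ml = model$biomarker$brain_conc),
    organs = organs,
    renal = model$renal,
    bidirectional = model$bidirectional,
    calibration = list(
      max_transfer_clearance = model$calibration$max_transfer_clearance,
      recovery_tau = model$calibration$recovery_tau
    )
  )
}

# Run one arm: settle to steady state, then (optionally) apply a maximal
# disruption event 60 min later and record the post-event peak.
run_arm <- function(subject, marker, calibration, include_skin = FALSE,
                    settle_duration = 1440, post_duration = 480,
                    dt = 0.5, with_event = TRUE) {
  base_model <- build_model(subject, marker, calibration,
                            include_skin = include_skin)
  settle <- simulate_serum(base_model, settle_duration, dt)
  ss <- detect_steady_state(settle)
  if (is.null(ss)) {
    ss <- list(conc = settle$serum_conc[length(settle$serum_conc)],
               time = settle_duration)
  }
  peak <- NA_real_
  event_result <- NULL
  if (with_event) {
    onset <- ss$time + 60
    ev <- disruption_event(onset, 100, calibration$recovery_tau)
    ev_model <- build_model(subject, marker, calibration,
                            include_skin = include_skin, events = list(ev))
    event_result <- simulate_serum(ev_model, onset + post_duration, dt)
    peak <- max(event_result$serum_conc[event_result$times >= onset])
  }
  list(steady_state = ss$conc, steady_time = ss$time,
       peak_post_bbbd = peak,
       echo = model_echo(base_model),
       settle = settle, event = event_result)
}

new_scenario_report <- function(name, arms_tbl, arms_detail, extra = list()) {
  structure(
    c(list(scenario_name = name, arms = arms_tbl,
           arm_details = arms_detail), extra),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s\n", x$scenario_name))
  print(x$arms)
  invisible(x)
}

#' Neonate versus adult biomarker kinetics
#'
#' For each marker, runs the neonate and adult-male presets from zero
#' initial serum to steady state, then applies one maximal disruption
#' event, and reports plateaus, post-disruption peaks, and the
#' neonate/adult steady-state fold-ratio. Neonatal brain marker
#' concentrations are kept equal to the adult values, so the age contrast
#' isolates anatomy (brain-to-blood volume ratio), steady-state BBB leak
#' (10% vs 2.5% of maximal) and kidney filtration.
#'
#' @param markers Character vector of shipped marker names, or a list of
#'   [biomarker()] objects.
#' @param calibration A `bbb_calibration`; defaults to the shared one.
#' @param with_event Include the disruption arm of the comparison.
#' @return A `scenario_report`; `$arms` is a tibble with one row per
#'   (marker, age class).
#' @export
run_age_comparison <- function(markers = "s100b_monomer",
                               calibration = default_calibration(),
                               with_event = TRUE) {
  marker_objs <- if (is.character(markers)) {
    lapply(markers, get_biomarker)
  } else markers
  subjects <- list(neonate = subject_preset("neonate"),
                   adult = subject_preset("adult_male"))
  rows <- list(); details <- list()
  for (m in marker_objs) {
    for (arm in names(subjects)) {
      res <- run_arm(subjects[[arm]], m, calibration,
                     with_event = with_event)
      rows[[length(rows) + 1]] <- tibble::tibble(
        marker = m$name, arm = arm,
        steady_state_ng_ml = res$steady_state,
        peak_post_bbbd_ng_ml = res$peak_post_bbbd
      )
      details[[paste(m$name, arm, sep = ".")]] <- res$echo
    }
  }
  arms <- dplyr::bind_rows(rows)
  ratios <- arms |>
    dplyr::select("marker", "arm", "steady_state_ng_ml") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = "steady_state_ng_ml") |>
    dplyr::mutate(fold_ratio = .data$neonate / .data$adult)
  new_scenario_report("age_comparison", arms, details,
                      list(fold_ratios = ratios))
}

#' Skin-pigmentation contribution to serum S100B
#'
#' Adult-male S100B model with the 7.8 l skin compartment enabled at a 2%
#' leak, contrasting the light-skin (0.288 ng/ml) and dark-skin
#' (2.0 ng/ml) skin tissue concentrations, plus a brain-only reference
#' arm. Each arm also reports the post-disruption peak increment, which
#' is expected to be nearly pigmentation-insensitive (disruption affects
#' cerebral vasculature only).
#'
#' @param calibration A `bbb_calibration`.
#' @return A `scenario_report` with one row per arm.
#' @export
run_pigmentation_comparison <- function(calibration = default_calibration()) {
  marker <- get_biomarker("s100b_monomer")
  arms_def <- list(
    brain_only = list(subject = subject_preset("adult_male"), skin = FALSE),
    light_skin = list(subject = subject_preset("light_skin"), skin = TRUE),
    dark_skin  = list(subject = subject_preset("dark_skin"), skin = TRUE)
  )
  rows <- list(); details <- list()
  for (arm in names(arms_def)) {
    d <- arms_def[[arm]]
    res <- run_arm(d$subject, marker, calibration, include_skin = d$skin)
    rows[[length(rows) + 1]] <- tibble::tibble(
      arm = arm,
      skin_conc_ng_ml = if (d$skin) d$subject$skin_marker_conc else 0,
      steady_state_ng_ml = res$steady_state,
      peak_post_bbbd_ng_ml = res$peak_post_bbbd,
      bbbd_increment_ng_ml = res$peak_post_bbbd - res$steady_state
    )
    details[[arm]] <- res$echo
  }
  new_scenario_report("pigmentation_comparison", dplyr::bind_rows(rows),
                      details)
}

#' Male versus female steady-state contrast
#'
#' Runs the adult male (brain 1.42 l, GFR coefficients 141/0.9) and adult
#' female (brain 1.05 l, coefficients 144/0.7) presets and reports both
#' plateaus and their relative difference. No threshold is asserted; the
#' expectation is that the physiological differences are small.
#'
#' @param calibration A `bbb_calibration`.
#' @param marker Shipped marker name.
#' @return A `scenario_report` with a `relative_difference` field.
#' @export
run_gender_comparison <- function(calibration = default_calibration(),
                                  marker = "s100b_monomer") {
  m <- get_biomarker(marker)
  rows <- list(); details <- list()
  for (arm in c("adult_male", "adult_female")) {
    res <- run_arm(subject_preset(arm), m, calibration, with_event = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      arm = arm, steady_state_ng_ml = res$steady_state
    )
    details[[arm]] <- res$echo
  }
  arms <- dplyr::bind_rows(rows)
  ss <- arms$steady_state_ng_ml
  rel_diff <- abs(ss[1] - ss[2]) / max(ss)
  new_scenario_report("gender_comparison", arms, details,
                      list(relative_difference = rel_diff))
}

#' Half-life surface over molecular weight and kidney health
#'
#' Elimination half-life at adult defaults for every combination of
#' molecular weight and kidney-health fraction, via the closed-form
#' physiology chain (GFR x filtration coefficient; brain/skin transfer
#' excluded so the table isolates renal elimination). `gfr_function = 0`
#' rows carry the infinite-half-life sentinel (`Inf`).
#'
#' @param mw_grid Molecular weights, daltons.
#' @param gfr_function_grid Kidney-health fractions in \[0, 1\].
#' @param subject Subject profile supplying GFR inputs and blood volume.
#' @return A tibble with columns `molecular_weight_da`, `gfr_function`,
#'   `half_life_min`.
#' @export
run_kidney_sweep <- function(mw_grid = c(10700, 21000, 26000, 46000, 140000),
                             gfr_function_grid = c(1, 0.75, 0.5, 0.25, 0.1),
                             subject = subject_preset("adult_male")) {
  if (!length(mw_grid) || !length(gfr_function_grid)) {
    abort("Both grids must be nonempty.", class = "neuropk_invalid_input")
  }
  grid <- tidyr::expand_grid(molecular_weight_da = mw_grid,
                             gfr_function = gfr_function_grid)
  vb_ml <- subject$blood_volume * 1000
  grid |>
    dplyr::mutate(
      half_life_min = purrr::map2_dbl(
        .data$molecular_weight_da, .data$gfr_function,
        function(mw, gf) {
          prof <- subject
          prof$gfr_function <- gf
          gfr <- compute_gfr(prof)
          elimination_half_life(
            renal_clearance(gfr, filtration_coefficient(mw)), vb_ml
          )
        }
      )
    )
}
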
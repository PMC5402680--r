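# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result into a tibble
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return A tibble with columns `time_min`, `serum_ng_ml`, `excreted_ng`,
#'   `influx_ng`, `index`.
#' @export
tidy.simulation_result <- function(x, ...) {
  tibble::tibble(
    time_min = x$times,
    serum_ng_ml = x$serum_conc,
    excreted_ng = x$excreted_mass,
    influx_ng = x$influx_mass,
    index = x$index
  )
}

#' One-row summary of a simulation
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return A tibble with the final concentration, steady-state
#'   diagnostics, mass-balance discrepancy and grid size.
#' @export
glance.simulation_result <- function(x, ...) {
  ss <- detect_steady_state(x)
  tibble::tibble(
    final_serum_ng_ml = x$serum_conc[length(x$serum_conc)],
    steady_state_ng_ml = if (is.null(ss)) NA_real_ else ss$conc,
    steady_state_min = if (is.null(ss)) NA_real_ else ss$time,
    mass_balance_ng = mass_balance(x),
    duration_min = max(x$times),
    n = length(x$times)
  )
}

#' Tidy a BBB calibration
#'
#' @param x A `bbb_calibration`.
#' @param ... Unused.
#' @return A tibble of (term, estimate) pairs.
#' @export
tidy.bbb_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("max_transfer_clearance_ml_min", "recovery_tau_min",
             "fit_residual_ng_ml"),
    estimate = c(x$max_transfer_clearance, x$recovery_tau, x$fit_residual)
  )
}

#' One-row summary of a BBB calibration
#'
#' @param x A `bbb_calibration`.
#' @param ... Unused.
#' @export
glance.bbb_calibration <- function(x, ...) {
  tibble::tibble(
    max_transfer_clearance_ml_min = x$max_transfer_clearance,
    recovery_tau_min = x$recovery_tau,
    fit_residual_ng_ml = x$fit_residual
  )
}

#' Tidy a scenario report
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return The per-arm tibble.
#' @export
tidy.scenario_report <- function(x, ...) x$arms

#' Plot a simulated serum time course
#'
#' Serum concentration against time, with disruption episodes (index above
#' the baseline leak) shaded.
#'
#' @param object A `simulation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_result <- function(object, ...) {
  df <- tidy(object)
  base_leak <- object$model$organs$brain$leak_fraction
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$serum_ng_ml)) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.6) +
    ggplot2::labs(
      x = "Time (min)", y = "Serum concentration (ng/ml)",
      title = sprintf("%s, %s %s", object$model$biomarker$name,
                      object$model$subject$age_class,
                      object$model$subject$sex)
    ) +
    ggplot2::theme_minimal()
  open <- df$index > base_leak + 1e-9
  if (any(open)) {
    shade <- df[open, ]
    p <- p + ggplot2::annotate(
      "rect", xmin = min(shade$time_min), xmax = max(shade$time_min),
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "#d95f0e"
    )
  }
  p
}

#' Plot a half-life sweep table
#'
#' Half-life against molecular weight, one line per kidney-health
#' fraction, log-log axes.
#'
#' @param sweep A tibble from [run_kidney_sweep()].
#' @return A ggplot object.
#' @export
plot_kidney_sweep <- function(sweep) {
  ggplot2::ggplot(
    dplyr::filter(sweep, is.finite(.data$half_life_min)),
    ggplot2::aes(x = .data$molecular_weight_da, y = .data$half_life_min,
                 colour = factor(.data$gfr_function),
                 group = .data$gfr_function)
  ) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Molecular weight (Da)", y = "Half-life (min)",
                  colour = "Kidney health") +
    ggplot2::theme_minimal()
}
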
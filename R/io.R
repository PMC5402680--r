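# Configuration loading, validation, and deterministic serialization.
#
# Config files are flat human-editable YAML with one nesting level
# (subject / biomarker / solver maps, plus a list of events). Unknown keys
# are rejected; every defaulted value is logged on the returned object.

config_known_keys <- list(
  top = c("subject", "biomarker", "include_skin", "bidirectional",
          "events", "solver", "outdir"),
  subject = c("preset", "age_class", "sex", "race", "height", "weight",
              "age", "serum_creatinine", "gfr_function",
              "body_surface_area", "brain_volume", "blood_volume",
              "skin_volume", "skin_marker_conc"),
  biomarker = c("name", "molecular_weight_da", "brain_conc_ng_ml"),
  event = c("onset_min", "peak_index", "recovery_tau_min"),
  solver = c("duration_min", "dt_min")
)

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, validates ranges
#' and contradictory settings (e.g. a neonate with the skin compartment),
#' and fills defaults for unset fields (adult-male preset, S100B monomer,
#' 1440 min at 0.5 min resolution). All problems are reported at once.
#' Every defaulted value is recorded in the `defaulted` field of the
#' returned config.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` with fields `subject`, `biomarker`,
#'   `include_skin`, `bidirectional`, `events`, `duration`, `dt`,
#'   `outdir`, `defaulted`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' does not exist.", path),
          class = "neuropk_validation_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  problems <- character()
  defaulted <- character()

  unknown <- setdiff(names(raw), config_known_keys$top)
  if (length(unknown)) {
    problems <- c(problems,
                  sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }

  note_default <- function(key, value) {
    defaulted <<- c(defaulted, sprintf("%s = %s (default)", key,
                                       paste(format(value), collapse = ",")))
  }

  # --- subject -------------------------------------------------------
  subject <- NULL
  sub_raw <- raw$subject
  if (is.null(sub_raw)) {
    note_default("subject", "adult_male")
    subject <- subject_preset("adult_male")
  } else if (is.character(sub_raw) && length(sub_raw) == 1) {
    subject <- tryCatch(subject_preset(sub_raw),
                        error = function(e) {
                          problems <<- c(problems, conditionMessage(e)); NULL
                        })
  } else if (is.list(sub_raw)) {
    unknown <- setdiff(names(sub_raw), config_known_keys$subject)
    if (length(unknown)) {
      problems <- c(problems, sprintf("unknown subject key(s): %s",
                                      paste(unknown, collapse = ", ")))
    } else {
      preset <- sub_raw$preset
      sub_raw$preset <- NULL
      base_args <- if (!is.null(preset)) {
        unclass(subject_preset(preset))
      } else list()
      args <- modifyList(base_args, sub_raw)
      args <- args[names(args) %in% names(formals(subject_profile))]
      subject <- tryCatch(do.call(subject_profile, args),
                          error = function(e) {
                            problems <<- c(problems, conditionMessage(e)); NULL
                          })
    }
  } else {
    problems <- c(problems, "`subject` must be a preset name or a map")
  }

  # --- biomarker -----------------------------------------------------
  marker <- NULL
  bm_raw <- raw$biomarker
  if (is.null(bm_raw)) {
    note_default("biomarker", "s100b_monomer")
    marker <- get_biomarker("s100b_monomer")
  } else if (is.character(bm_raw) && length(bm_raw) == 1) {
    marker <- tryCatch(get_biomarker(bm_raw),
                       error = function(e) {
                         problems <<- c(problems, conditionMessage(e)); NULL
                       })
  } else if (is.list(bm_raw)) {
    unknown <- setdiff(names(bm_raw), config_known_keys$biomarker)
    if (length(unknown)) {
      problems <- c(problems, sprintf("unknown biomarker key(s): %s",
                                      paste(unknown, collapse = ", ")))
    } else {
      marker <- tryCatch(
        biomarker(bm_raw$name %||% "custom",
                  bm_raw$molecular_weight_da,
                  bm_raw$brain_conc_ng_ml),
        error = function(e) {
          problems <<- c(problems, conditionMessage(e)); NULL
        })
    }
  } else {
    problems <- c(problems, "`biomarker` must be a marker name or a map")
  }

  # --- flags, events, solver ----------------------------------------
  include_skin <- isTRUE(raw$include_skin)
  if (is.null(raw$include_skin)) note_default("include_skin", FALSE)
  bidirectional <- if (is.null(raw$bidirectional)) {
    note_default("bidirectional", TRUE); TRUE
  } else isTRUE(raw$bidirectional)

  if (include_skin && !is.null(subject) && subject$age_class == "neonate") {
    problems <- c(problems,
                  "contradictory config: skin compartment with a neonate subject")
  }

  events <- list()
  for (i in seq_along(raw$events)) {
    ev <- raw$events[[i]]
    unknown <- setdiff(names(ev), config_known_keys$event)
    if (length(unknown)) {
      problems <- c(problems, sprintf("event %d: unknown key(s) %s", i,
                                      paste(unknown, collapse = ", ")))
      next
    }
    events[[i]] <- tryCatch(
      disruption_event(ev$onset_min, ev$peak_index %||% 100,
                       ev$recovery_tau_min %||% 8.8),
      error = function(e) {
        problems <<- c(problems, sprintf("event %d: %s", i,
                                         conditionMessage(e)))
        NULL
      })
  }
  events <- events[!vapply(events, is.null, logical(1))]

  solver <- raw$solver %||% list()
  unknown <- setdiff(names(solver), config_known_keys$solver)
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown solver key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  duration <- solver$duration_min %||% {
    note_default("solver.duration_min", 1440); 1440
  }
  dt <- solver$dt_min %||% { note_default("solver.dt_min", 0.5); 0.5 }
  problems <- c(problems,
                check_scalar_number(duration, "solver.duration_min",
                                    min = 0, strict_min = TRUE),
                check_scalar_number(dt, "solver.dt_min",
                                    min = 0, strict_min = TRUE))

  outdir <- raw$outdir %||% { note_default("outdir", "."); "." }

  if (length(problems)) {
    abort(paste0("Config validation failed:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "neuropk_validation_error")
  }
  structure(
    list(subject = subject, biomarker = marker,
         include_skin = include_skin, bidirectional = bidirectional,
         events = events, duration = duration, dt = dt, outdir = outdir,
         defaulted = defaulted),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Builds the model described by a [load_config()] result, simulates it,
#' and assembles the run report (resolved-parameter echo, steady-state
#' diagnostics, mass balance, calibration used).
#'
#' @param config A `run_config`.
#' @param calibration A `bbb_calibration`; defaults to the shared one.
#' @return A list with `result` (a `simulation_result`) and `report`
#'   (a list, serializable to JSON).
#' @export
run_from_config <- function(config, calibration = default_calibration()) {
  stopifnot(inherits(config, "run_config"))
  model <- build_model(config$subject, config$biomarker, calibration,
                       include_skin = config$include_skin,
                       events = config$events,
                       bidirectional = config$bidirectional)
  result <- simulate_serum(model, config$duration, config$dt)
  ss <- detect_steady_state(result)
  report <- list(
    model = model_echo(model),
    solver = list(duration_min = config$duration, dt_min = config$dt,
                  rtol = 1e-8, atol = 1e-12),
    steady_state = if (is.null(ss)) NULL else
      list(conc_ng_ml = ss$conc, time_min = ss$time),
    mass_balance_ng = mass_balance(result),
    analytic_steady_state_ng_ml = if (length(config$events) == 0)
      analytic_steady_state(model) else NULL,
    defaulted = as.list(config$defaulted)
  )
  list(result = result, report = report)
}

# Fixed-precision formatting (9 significant digits) for reproducible,
# diff-able outputs.
fmt9 <- function(x) {
  ifelse(is.finite(x), formatC(x, digits = 9, format = "g"), as.character(x))
}

#' Write run outputs deterministically
#'
#' Writes the time-series CSV (`timeseries.csv`, header
#' `time_min,serum_ng_ml,excreted_ng,influx_ng,index`), the run report
#' (`report.json`) and a short log (`run.log`) into `outdir`. All numbers
#' are formatted at 9 significant digits, so re-running an identical
#' configuration reproduces byte-identical files.
#'
#' @param result A `simulation_result`.
#' @param report The report list from [run_from_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, report, outdir) {
  stopifnot(inherits(result, "simulation_result"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", outdir),
          class = "neuropk_io_error")
  }
  csv_path <- file.path(outdir, "timeseries.csv")
  lines <- c(
    "time_min,serum_ng_ml,excreted_ng,influx_ng,index",
    paste(fmt9(result$times), fmt9(result$serum_conc),
          fmt9(result$excreted_mass), fmt9(result$influx_mass),
          fmt9(result$index), sep = ",")
  )
  writeLines(lines, csv_path)

  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = I(9),
                       pretty = TRUE, null = "null")

  log_path <- file.path(outdir, "run.log")
  log_lines <- c(
    sprintf("marker: %s", result$model$biomarker$name),
    sprintf("subject: %s %s", result$model$subject$age_class,
            result$model$subject$sex),
    sprintf("renal clearance (ml/min): %s",
            fmt9(result$model$renal$renal_clearance)),
    sprintf("final serum (ng/ml): %s",
            fmt9(result$serum_conc[length(result$serum_conc)])),
    unlist(report$defaulted)
  )
  writeLines(log_lines, log_path)
  invisible(c(csv = csv_path, json = json_path, log = log_path))
}
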
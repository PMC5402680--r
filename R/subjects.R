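# Subject profiles, presets, and biomarker definitions.

#' Construct a subject profile
#'
#' Bundles the demographic and anatomic parameters that determine
#' clearances and compartment volumes. Volumes are in liters; serum
#' creatinine in mg/dl; `gfr_function` is the 0-1 kidney-health fraction.
#' `body_surface_area` (m2) is used only for neonates, whose GFR is
#' BSA-scaled rather than creatinine-based.
#'
#' @param age_class `"neonate"` or `"adult"`.
#' @param sex `"male"` or `"female"`.
#' @param race `"caucasian"` or `"african_american"` (selects the GFR
#'   coefficient set).
#' @param height,weight Height (m) and weight (kg).
#' @param age Age in years; standardised to 45 for adults since the GFR
#'   age term varies little over adulthood.
#' @param serum_creatinine Serum creatinine, mg/dl. Defaults to the
#'   sex-specific reference value so the creatinine term is inert.
#' @param gfr_function Kidney-health fraction in \[0, 1\].
#' @param body_surface_area BSA in m2 (neonates).
#' @param brain_volume,blood_volume,skin_volume Compartment volumes, liters.
#' @param skin_marker_conc Marker tissue concentration in skin, ng/ml.
#' @return A `subject_profile` object (list).
#' @seealso [subject_preset()] for the shipped presets.
#' @export
subject_profile <- function(age_class = c("adult", "neonate"),
                            sex = c("male", "female"),
                            race = c("caucasian", "african_american"),
                            height = 1.80, weight = 80, age = 45,
                            serum_creatinine = NULL,
                            gfr_function = 1,
                            body_surface_area = 0.25,
                            brain_volume = NULL, blood_volume = NULL,
                            skin_volume = 7.8,
                            skin_marker_conc = 0.288) {
  age_class <- match.arg(age_class)
  sex <- match.arg(sex)
  race <- match.arg(race)
  if (is.null(serum_creatinine)) {
    serum_creatinine <- gfr_coefficients(sex, race)$B
  }
  if (is.null(brain_volume)) {
    brain_volume <- if (age_class == "neonate") 0.42
                    else if (sex == "male") 1.42 else 1.05
  }
  if (is.null(blood_volume)) {
    blood_volume <- if (age_class == "neonate") 0.28 else 6.0
  }
  stop_invalid(c(
    check_scalar_number(height, "height", min = 0, strict_min = TRUE),
    check_scalar_number(weight, "weight", min = 0, strict_min = TRUE),
    check_scalar_number(age, "age", min = 0),
    check_scalar_number(serum_creatinine, "serum_creatinine",
                        min = 0, strict_min = TRUE),
    check_scalar_number(gfr_function, "gfr_function", 0, 1),
    check_scalar_number(body_surface_area, "body_surface_area",
                        min = 0, strict_min = TRUE),
    check_scalar_number(brain_volume, "brain_volume",
                        min = 0, strict_min = TRUE),
    check_scalar_number(blood_volume, "blood_volume",
                        min = 0, strict_min = TRUE),
    check_scalar_number(skin_volume, "skin_volume",
                        min = 0, strict_min = TRUE),
    check_scalar_number(skin_marker_conc, "skin_marker_conc", min = 0)
  ))
  structure(
    list(
      age_class = age_class, sex = sex, race = race,
      height = height, weight = weight, age = age,
      serum_creatinine = serum_creatinine, gfr_function = gfr_function,
      body_surface_area = body_surface_area,
      brain_volume = brain_volume, blood_volume = blood_volume,
      skin_volume = skin_volume, skin_marker_conc = skin_marker_conc
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> %s %s (%s)\n  brain %.2f l, blood %.2f l, GFR function %.2f\n",
    x$age_class, x$sex, x$race, x$brain_volume, x$blood_volume, x$gfr_function
  ))
  invisible(x)
}

#' Named subject presets
#'
#' Shipped presets mirroring the modeled populations: `neonate`
#' (brain 0.42 l, blood 0.28 l, BSA 0.25 m2), `adult_male` (brain 1.42 l,
#' blood 6.0 l), `adult_female` (brain 1.05 l), `adult_male_aa`
#' (African-American GFR coefficients), and `light_skin` / `dark_skin`
#' (adult male with skin S100B at 0.288 resp. 2.0 ng/ml).
#'
#' @param name Preset key.
#' @return A [subject_profile()].
#' @export
subject_preset <- function(name = c("adult_male", "adult_female",
                                    "adult_male_aa", "neonate",
                                    "light_skin", "dark_skin")) {
  name <- match.arg(name)
  switch(name,
    adult_male    = subject_profile("adult", "male"),
    adult_female  = subject_profile("adult", "female"),
    adult_male_aa = subject_profile("adult", "male", "african_american"),
    neonate       = subject_profile("neonate", "male"),
    light_skin    = subject_profile("adult", "male", skin_marker_conc = 0.288),
    dark_skin     = subject_profile("adult", "male", skin_marker_conc = 2.0)
  )
}

#' Define a biomarker
#'
#' The physicochemical identity of a marker: molecular weight (drives the
#' glomerular filtration coefficient) and tissue concentrations (drive
#' source strength).
#'
#' @param name Marker name.
#' @param molecular_weight Molecular weight in daltons.
#' @param brain_conc Brain tissue concentration, ng/ml.
#' @param organ_concs Named numeric vector of extracranial tissue
#'   concentrations (ng/ml), e.g. `c(skin = 0.288)`.
#' @return A `biomarker` object.
#' @export
biomarker <- function(name, molecular_weight, brain_conc,
                      organ_concs = c()) {
  stop_invalid(c(
    check_scalar_number(molecular_weight, "molecular_weight",
                        min = 0, strict_min = TRUE),
    check_scalar_number(brain_conc, "brain_conc", min = 0),
    if (length(organ_concs) && any(organ_concs < 0))
      "`organ_concs` must be non-negative"
  ))
  structure(
    list(name = name, molecular_weight = molecular_weight,
         brain_conc = brain_conc, organ_concs = organ_concs),
    class = "biomarker"
  )
}

#' @export
print.biomarker <- function(x, ...) {
  cat(sprintf("<biomarker> %s: %g Da, brain %g ng/ml\n",
              x$name, x$molecular_weight, x$brain_conc))
  invisible(x)
}

#' The shipped biomarker panel
#'
#' The four modeled markers with their molecular weights and brain tissue
#' concentrations: S100B monomer (10.7 kD, 10 ng/ml), S100B homodimer
#' (21 kD, 10 ng/ml), GFAP (26 kD, 1 ng/ml) and UCHL-1 (26 kD,
#' 7.6 ng/ml). S100B additionally carries a default light-skin tissue
#' concentration of 0.288 ng/ml.
#'
#' @return A tibble with columns `name`, `molecular_weight_da`,
#'   `brain_conc_ng_ml`, `skin_conc_ng_ml`.
#' @export
biomarker_panel <- function() {
  path <- system.file("extdata", "biomarkers.tsv", package = "neuropk")
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Look up a shipped biomarker by name
#'
#' @param name One of `"s100b_monomer"`, `"s100b_dimer"`, `"gfap"`,
#'   `"uchl1"`.
#' @return A [biomarker()].
#' @export
get_biomarker <- function(name) {
  panel <- biomarker_panel()
  row <- panel[panel$name == name, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown biomarker '%s'; shipped markers: %s", name,
                  paste(panel$name, collapse = ", ")),
          class = "neuropk_invalid_input")
  }
  organ <- if (is.finite(row$skin_conc_ng_ml) && row$skin_conc_ng_ml > 0) {
    c(skin = row$skin_conc_ng_ml)
  } else c()
  biomarker(row$name, row$molecular_weight_da, row$brain_conc_ng_ml, organ)
}
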
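# Closed-form anthropometric and renal physiology.
#
# Canonical units: ng, ml, min. Volumes are stored in liters on profile
# objects and converted to ml where rates are computed.

# Reference adult male brain volume (liters) against which organ maximal
# transfer clearances are volume-scaled.
REF_BRAIN_VOLUME_L <- 1.42

# Neonatal glomerular filtration preset, ml/min normalised to 1.73 m2 BSA.
NEONATAL_GFR_PER_173 <- 47

#' Total blood volume from Nadler's formula
#'
#' Estimates total blood volume (volemia) from height, weight and sex.
#' Two dialects are provided: `"nadler_cubic"` (the default) uses the
#' canonical Nadler formula in which the height term is cubed, while
#' `"as_printed"` uses a height-linear variant of the same coefficients.
#' The linear variant yields implausibly small volumes for typical adults
#' (about 3.8 l for a 1.80 m, 80 kg male) and is retained only for
#' comparison; the cubic form is physiologic.
#'
#' @param height Height in meters.
#' @param weight Weight in kilograms.
#' @param sex `"male"` or `"female"`.
#' @param dialect `"nadler_cubic"` (default) or `"as_printed"`.
#' @return Total blood volume in liters.
#' @examples
#' compute_tbv(1.80, 80, "male") # ~5.32 l
#' @export
compute_tbv <- function(height, weight, sex = c("male", "female"),
                        dialect = c("nadler_cubic", "as_printed")) {
  sex <- match.arg(sex)
  dialect <- match.arg(dialect)
  stop_invalid(c(
    check_scalar_number(height, "height", min = 0, strict_min = TRUE),
    check_scalar_number(weight, "weight", min = 0, strict_min = TRUE)
  ))
  h <- if (dialect == "nadler_cubic") height^3 else height
  if (sex == "male") {
    0.3669 * h + 0.03219 * weight + 0.6041
  } else {
    0.3561 * h + 0.03308 * weight + 0.1833
  }
}

# Sex/race GFR coefficient table (CKD-EPI-style coefficients).
gfr_coefficients <- function(sex, race) {
  A <- switch(race,
    caucasian        = c(male = 141, female = 144),
    african_american = c(male = 163, female = 166)
  )[[sex]]
  B <- c(male = 0.9, female = 0.7)[[sex]]
  list(A = A, B = B)
}

#' Glomerular filtration rate for an adult profile
#'
#' Computes GFR (ml/min) as
#' `gfr_function * A * (SrCr/B)^exp * 0.993^age`, with sex- and
#' race-specific coefficients `A` (141/144 Caucasian male/female, 163/166
#' African-American male/female) and `B` (0.9 male, 0.7 female). The
#' creatinine exponent is -1.209 when `SrCr/B > 1` and 0 otherwise, so a
#' creatinine at the sex-specific reference value leaves the term inert and
#' an elevated creatinine lowers GFR. Age defaults to 45 years on profiles;
#' the age term varies the result by little over the adult range.
#' `gfr_function` is a 0-1 kidney-health multiplier (1 healthy, 0 failure).
#'
#' @param profile A [subject_profile()] with `age_class = "adult"`.
#' @param per_hour If `TRUE`, return ml/h (the ml/min value times 60).
#' @return GFR in ml/min (or ml/h).
#' @seealso [neonatal_gfr()] for neonates.
#' @export
compute_gfr <- function(profile, per_hour = FALSE) {
  stopifnot(inherits(profile, "subject_profile"))
  if (profile$age_class != "adult") {
    abort("`compute_gfr()` supports adult profiles only; use `neonatal_gfr()`.",
          class = "neuropk_unsupported")
  }
  stop_invalid(check_scalar_number(profile$gfr_function, "gfr_function", 0, 1))
  co <- gfr_coefficients(profile$sex, profile$race)
  ratio <- profile$serum_creatinine / co$B
  ex <- if (ratio > 1) -1.209 else 0
  gfr <- profile$gfr_function * co$A * ratio^ex * 0.993^profile$age
  if (per_hour) gfr * 60 else gfr
}

#' Neonatal glomerular filtration rate
#'
#' Neonatal kidney filtration is preset to 47 ml/min per 1.73 m2 of body
#' surface area; the absolute rate is obtained by scaling to the neonate's
#' BSA.
#'
#' @param body_surface_area BSA in m2.
#' @param gfr_function Kidney-health fraction in \[0, 1\].
#' @return GFR in ml/min.
#' @export
neonatal_gfr <- function(body_surface_area, gfr_function = 1) {
  stop_invalid(c(
    check_scalar_number(body_surface_area, "body_surface_area",
                        min = 0, strict_min = TRUE),
    check_scalar_number(gfr_function, "gfr_function", 0, 1)
  ))
  gfr_function * NEONATAL_GFR_PER_173 * (body_surface_area / 1.73)
}

#' Glomerular filtration coefficient for a protein
#'
#' Fraction of a protein's plasma clearance achieved by glomerular
#' filtration (the sieving coefficient `C_F`), a decreasing sigmoid of
#' molecular weight:
#' `C_F = -0.04094 + 1.19614 / (1 + 10^((27096 - MW) * -3.1e-5))`,
#' clamped to \[0, 1\] (the raw curve reaches ~1.004 as MW -> 0 and
#' -0.041 as MW -> Inf). Small proteins filter nearly freely; above
#' ~60 kD filtration is negligible.
#'
#' @param molecular_weight Molecular weight in daltons (vectorised).
#' @return Filtration coefficient(s) in \[0, 1\].
#' @examples
#' filtration_coefficient(10700) # S100B monomer, ~0.87
#' @export
filtration_coefficient <- function(molecular_weight) {
  if (!is.numeric(molecular_weight) || any(!is.finite(molecular_weight)) ||
      any(molecular_weight <= 0)) {
    abort("`molecular_weight` must be positive and finite (daltons).",
          class = "neuropk_invalid_input")
  }
  raw <- -0.04094 + 1.19614 / (1 + 10^((27096 - molecular_weight) * -3.1e-5))
  pmin(1, pmax(0, raw))
}

#' Renal clearance of a protein
#'
#' Plasma clearance through the kidney: GFR times the molecular-weight
#' dependent filtration coefficient. Elimination is glomerular only (no
#' tubular secretion or reabsorption).
#'
#' @param gfr GFR in ml/min.
#' @param c_f Filtration coefficient in \[0, 1\].
#' @return Clearance in ml/min.
#' @export
renal_clearance <- function(gfr, c_f) {
  stop_invalid(c(
    check_scalar_number(gfr, "gfr", min = 0),
    check_scalar_number(c_f, "c_f", 0, 1)
  ))
  gfr * c_f
}

#' Single-compartment elimination half-life
#'
#' First-order elimination from a well-mixed blood pool:
#' `t1/2 = ln(2) * V_blood / CL_total`. A total clearance of zero returns
#' `Inf` — the explicit no-elimination sentinel (complete kidney failure).
#'
#' @param total_clearance Total clearance in ml/min (>= 0).
#' @param blood_volume Blood volume in ml.
#' @return Half-life in minutes (`Inf` when clearance is zero).
#' @export
elimination_half_life <- function(total_clearance, blood_volume) {
  stop_invalid(c(
    check_scalar_number(total_clearance, "total_clearance", min = 0),
    check_scalar_number(blood_volume, "blood_volume", min = 0,
                        strict_min = TRUE)
  ))
  if (total_clearance == 0) return(Inf)
  log(2) * blood_volume / total_clearance
}
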
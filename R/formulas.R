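#' Body surface area
#'
#' DuBois: `0.007184 * height^0.725 * weight^0.425`;
#' Mosteller: `sqrt(height * weight / 3600)`. DuBois is the default, being
#' the formula most prevalent in the cohorts behind normative CMR tables.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return BSA in m^2.
#' @export
#' @examples
#' bsa(180, 80, "mosteller")  # exactly 2
bsa <- function(height_cm, weight_kg, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  stopifnot(is.numeric(height_cm), is.numeric(weight_kg))
  if (any(!is.finite(height_cm) | height_cm <= 0) ||
      any(!is.finite(weight_kg) | weight_kg <= 0))
    stop_domain("height and weight must be positive")
  switch(formula,
         dubois    = 0.007184 * height_cm^0.725 * weight_kg^0.425,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' Index a value to body surface area
#'
#' @param value absolute value.
#' @param bsa body surface area in m^2 (> 0).
#' @return `value / bsa`.
#' @export
index_value <- function(value, bsa) {
  stopifnot(is.numeric(value), is.numeric(bsa))
  if (any(!is.finite(bsa) | bsa <= 0)) stop_domain("`bsa` must be positive")
  value / bsa
}

#' Atrial volume by the biplane area-length (ellipsoid) method
#'
#' `V = (8 / (3 * pi)) * A1 * A2 / L`, with A1 and A2 the atrial areas in the
#' four- and two-chamber views (cm^2) and L either the shortest of the two
#' cavity lengths (the pediatric convention) or their mean.
#'
#' @param area_4ch,area_2ch planimetered areas, cm^2.
#' @param length_4ch,length_2ch cavity long-axis lengths, cm.
#' @param length_rule `"shortest"` (default) or `"mean"`.
#' @return volume in mL.
#' @export
atrial_volume_biplane_ellipsoid <- function(area_4ch, area_2ch,
                                            length_4ch, length_2ch,
                                            length_rule = c("shortest", "mean")) {
  length_rule <- match.arg(length_rule)
  stopifnot(is.numeric(area_4ch), is.numeric(area_2ch),
            is.numeric(length_4ch), is.numeric(length_2ch))
  if (any(length_4ch <= 0) || any(length_2ch <= 0))
    stop_domain("cavity lengths must be positive")
  L <- switch(length_rule,
              shortest = pmin(length_4ch, length_2ch),
              mean = (length_4ch + length_2ch) / 2)
  (8 / (3 * pi)) * area_4ch * area_2ch / L
}

#' Atrial volume by the calibrated biplane area-length formula
#'
#' The empirically calibrated variant
#' `V = 0.848 * A4ch * A2ch / ((L2ch + L4ch) / 2)`; its constant is within
#' 0.1% of the ellipsoid constant `8 / (3 * pi)`, so the two mean-length
#' variants are nearly identical.
#'
#' @inheritParams atrial_volume_biplane_ellipsoid
#' @return volume in mL.
#' @export
atrial_volume_biplane_calibrated <- function(area_4ch, area_2ch,
                                             length_4ch, length_2ch) {
  if (any(length_4ch <= 0) || any(length_2ch <= 0))
    stop_domain("cavity lengths must be positive")
  0.848 * area_4ch * area_2ch / ((length_2ch + length_4ch) / 2)
}

#' Atrial volume by the monoplane area-length method
#'
#' `V = 8 * A^2 / (3 * pi * L)`: the biplane ellipsoid formula with the
#' single-view area used for both planes.
#'
#' @param area atrial area, cm^2.
#' @param length cavity long-axis length, cm.
#' @return volume in mL.
#' @export
atrial_volume_monoplane <- function(area, length) {
  if (any(length <= 0)) stop_domain("cavity length must be positive")
  8 * area^2 / (3 * pi * length)
}

#' Left-ventricular sphericity index
#'
#' Ratio of the cavity volume to the volume of a sphere whose diameter is the
#' four-chamber cavity length: `EDV / ((4/3) * pi * (length/2)^3)`. A perfect
#' sphere scores 1; a normal, bullet-shaped LV scores well below 1.
#'
#' @param edv end-diastolic volume, mL.
#' @param length_4ch four-chamber cavity length, cm.
#' @return dimensionless index.
#' @export
sphericity_index <- function(edv, length_4ch) {
  if (any(length_4ch <= 0)) stop_domain("cavity length must be positive")
  edv / ((4 * pi / 3) * (length_4ch / 2)^3)
}

#' Aortic distensibility
#'
#' `(Amax - Amin) / (Amin * (Pmax - Pmin))`, reported in 10^-3 mmHg^-1.
#' The area ratio makes the result independent of the area unit.
#'
#' @param a_max,a_min maximal and minimal cross-sectional areas (same unit).
#' @param p_max,p_min systolic and diastolic blood pressure, mmHg.
#' @return distensibility in 10^-3 mmHg^-1.
#' @export
#' @examples
#' distensibility(1.1, 1.0, 120, 80)  # 2.5
distensibility <- function(a_max, a_min, p_max, p_min) {
  stopifnot(is.numeric(a_max), is.numeric(a_min))
  if (any(a_min <= 0)) stop_domain("`a_min` must be positive")
  if (any(p_max <= p_min)) stop_domain("pulse pressure must be positive (p_max > p_min)")
  1000 * (a_max - a_min) / (a_min * (p_max - p_min))
}

#' Extracellular volume fraction from pre/post-contrast T1
#'
#' `ECV = (1 - Hct) * dR1_myo / dR1_blood`, where `dR1 = 1/T1_post -
#' 1/T1_native`.
#'
#' @param t1_myo_native,t1_myo_post myocardial T1 before/after contrast, ms.
#' @param t1_blood_native,t1_blood_post blood-pool T1 before/after contrast, ms.
#' @param hematocrit hematocrit fraction in (0, 1).
#' @return ECV as a fraction.
#' @export
ecv <- function(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post,
                hematocrit) {
  ts <- c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post)
  if (any(!is.finite(ts) | ts <= 0)) stop_domain("all T1 times must be positive")
  if (!is_num1(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop_domain("hematocrit must be in (0, 1)")
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_native
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_native
  if (dr1_blood == 0) stop_domain("blood delta-R1 is zero")
  (1 - hematocrit) * dr1_myo / dr1_blood
}

#' Synthetic hematocrit from native blood T1
#'
#' `Hct = slope * (1/T1_blood_native) + intercept`. Calibrations are scanner-
#' and sequence-specific, so no default coefficients are shipped; the caller
#' must supply the local calibration. Results are clipped to (0, 1) with a
#' warning.
#'
#' @param t1_blood_native native blood T1, ms.
#' @param calibration numeric vector `c(slope, intercept)` on the 1/T1 scale.
#' @return estimated hematocrit fraction.
#' @export
synthetic_hct <- function(t1_blood_native, calibration) {
  if (missing(calibration) || is.null(calibration) || length(calibration) != 2L)
    stop_domain("a site-specific `calibration` c(slope, intercept) is required")
  if (any(!is.finite(t1_blood_native) | t1_blood_native <= 0))
    stop_domain("native blood T1 must be positive")
  h <- calibration[1] * (1 / t1_blood_native) + calibration[2]
  if (any(h <= 0 | h >= 1)) {
    warning("synthetic hematocrit clipped to (0, 1)")
    h <- pmin(pmax(h, 1e-6), 1 - 1e-6)
  }
  h
}

#' R2* relaxation rate from T2*
#'
#' @param t2star T2* in ms (> 0).
#' @return R2* in s^-1 (`1000 / t2star`).
#' @export
r2star <- function(t2star) {
  if (any(!is.finite(t2star) | t2star <= 0)) stop_domain("T2* must be positive")
  1000 / t2star
}

#' Cardiac iron concentration from T2*
#'
#' `[Fe] = 45 * T2*^-1.22`, in mg per g dry weight, with T2* in ms.
#'
#' @param t2star T2* in ms (> 0).
#' @return iron concentration, mg/g dry weight.
#' @export
iron_concentration <- function(t2star) {
  if (any(!is.finite(t2star) | t2star <= 0)) stop_domain("T2* must be positive")
  45 * t2star^(-1.22)
}

#' Grade myocardial iron load from T2*
#'
#' Severity grading by field strength: at 1.5T, normal above 20 ms, iron
#' overload for 10-20 ms, severe below 10 ms; at 3T the thresholds are
#' 12 ms and 5.5 ms. A value exactly on a threshold is assigned to the
#' milder of the two adjoining classes below it (e.g. T2* = 20 ms at 1.5T
#' is "overload" because normal requires > 20), so the three classes
#' partition (0, Inf) without gaps or overlap.
#'
#' @param t2star T2* in ms (> 0); vectorized.
#' @param field `"1.5T"` or `"3T"`.
#' @return factor with levels `normal`, `overload`, `severe`.
#' @export
#' @examples
#' grade_iron(c(25, 15, 4), "1.5T")
grade_iron <- function(t2star, field = c("1.5T", "3T")) {
  field <- match.arg(field)
  if (any(!is.finite(t2star) | t2star <= 0)) stop_domain("T2* must be positive")
  th <- switch(field, "1.5T" = c(severe = 10, normal = 20),
                      "3T"   = c(severe = 5.5, normal = 12))
  out <- ifelse(t2star > th["normal"], "normal",
                ifelse(t2star < th["severe"], "severe", "overload"))
  factor(out, levels = c("normal", "overload", "severe"))
}

#' Stage aortic stenosis from CMR criteria
#'
#' Staging by maximum transvalvular velocity (mild 2.0-2.9 m/s, moderate
#' 3.0-3.9, severe >= 4, very severe >= 5) and/or orifice area (severe at
#' <= 1.0 cm^2, or <= 0.6 cm^2/m^2 indexed to BSA). When several criteria are
#' supplied the worst stage wins.
#'
#' @param v_max maximum velocity, m/s (optional).
#' @param orifice_area effective orifice area, cm^2 (optional).
#' @param area_bsa orifice area indexed to BSA, cm^2/m^2 (optional).
#' @return list with `stage` (`"none"`, `"mild"`, `"moderate"`, `"severe"`),
#'   `very_severe` flag and `criteria` (named stages per supplied criterion).
#' @export
#' @examples
#' stage_aortic_stenosis(v_max = 4.2)
stage_aortic_stenosis <- function(v_max = NULL, orifice_area = NULL,
                                  area_bsa = NULL) {
  if (is.null(v_max) && is.null(orifice_area) && is.null(area_bsa))
    stop_domain("supply at least one of v_max, orifice_area, area_bsa")
  lev <- c("none", "mild", "moderate", "severe")
  crit <- list()
  very <- FALSE
  if (!is.null(v_max)) {
    stopifnot(is_num1(v_max), v_max >= 0)
    crit$v_max <- if (v_max >= 4) "severe" else if (v_max >= 3) "moderate"
                  else if (v_max >= 2) "mild" else "none"
    very <- v_max >= 5
  }
  if (!is.null(orifice_area)) {
    stopifnot(is_num1(orifice_area), orifice_area > 0)
    crit$orifice_area <- if (orifice_area <= 1.0) "severe" else "none"
  }
  if (!is.null(area_bsa)) {
    stopifnot(is_num1(area_bsa), area_bsa > 0)
    crit$area_bsa <- if (area_bsa <= 0.6) "severe" else "none"
  }
  stage <- lev[max(match(unlist(crit), lev))]
  list(stage = stage, very_severe = very, criteria = crit)
}

#' Classify left-ventricular diastolic function
#'
#' Rule table on mitral deceleration time (MDT) and the E/A ratio of the
#' mitral inflow profile: normal has MDT 150-220 ms with E/A 1-2; type 1
#' (impaired relaxation) has increased MDT with E/A < 1; type 2
#' (pseudonormal) has normal MDT with E/A 1-2; type 3 (restrictive) has
#' decreased MDT with E/A > 2. Normal and pseudonormal filling are not
#' separable on these two inputs alone, so both are returned in that case
#' rather than forcing a guess.
#'
#' @param mdt mitral deceleration time, ms.
#' @param ea_ratio E/A ratio.
#' @return character vector of the classes consistent with the inputs
#'   (subset of `"normal"`, `"type1"`, `"type2"`, `"type3"`); empty when no
#'   class matches.
#' @export
#' @examples
#' classify_diastolic(300, 0.8)  # "type1"
#' classify_diastolic(180, 1.5)  # c("normal", "type2")
classify_diastolic <- function(mdt, ea_ratio) {
  stopifnot(is_num1(mdt), is_num1(ea_ratio))
  if (mdt <= 0 || ea_ratio <= 0) stop_domain("MDT and E/A ratio must be positive")
  mdt_class <- if (mdt > 220) "increased" else if (mdt < 150) "decreased" else "normal"
  out <- character(0)
  if (mdt_class == "normal" && ea_ratio >= 1 && ea_ratio <= 2)
    out <- c(out, "normal", "type2")
  if (mdt_class == "increased" && ea_ratio < 1)
    out <- c(out, "type1")
  if (mdt_class == "decreased" && ea_ratio > 2)
    out <- c(out, "type3")
  out
}
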
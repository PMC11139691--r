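#' Parameters of the 2021 CKD-EPI creatinine--cystatin C equation
#'
#' Constants of the race-free 2021 CKD-EPI combined equation. The equation is
#'
#' \deqn{eGFR = 135 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-0.544} \cdot \min(Scys/0.8, 1)^{-0.323} \cdot
#'   \max(Scys/0.8, 1)^{-0.778} \cdot 0.9961^{age} \cdot 1.08[\mathrm{female}]}
#'
#' with creatinine Scr in mg/dL (\eqn{\kappa} = 0.7 female / 0.9 male,
#' \eqn{\alpha} = -0.219 female / -0.144 male) and cystatin C Scys in mg/L.
#' Serum creatinine supplied in µmol/L is converted with the factor
#' 1/88.42. Keeping the constants in a parameter object allows the
#' creatinine-only or cystatin-only 2021 variants to be configured without
#' code changes.
#'
#' @return named list of equation constants.
#' @export
egfr_params_2021 <- function() {
  list(
    scale = 135,
    kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.219, male = -0.144),
    creatinine_high_exp = -0.544,
    cystatin_knot = 0.8,
    cystatin_low_exp = -0.323,
    cystatin_high_exp = -0.778,
    age_base = 0.9961,
    female_multiplier = 1.08,
    umol_per_mgdl = 88.42
  )
}

#' Estimated GFR from serum creatinine and cystatin C
#'
#' Evaluates the 2021 CKD-EPI combined creatinine--cystatin C equation
#' (see [egfr_params_2021()]). Strictly decreasing in creatinine, cystatin C
#' and age at fixed sex.
#'
#' @param creatinine serum creatinine in µmol/L (the cohort's unit). Values
#'   below 15 trigger a warning because they suggest mg/dL input.
#' @param cystatin_c serum cystatin C in mg/L.
#' @param age age at the blood draw, years.
#' @param sex `"male"` / `"female"` (vector recycled against the analytes).
#' @param params equation constants, [egfr_params_2021()].
#' @return eGFR in mL/min per 1.73 m², same length as the inputs.
#' @examples
#' egfr_cr_cys(84, 0.92, 69, "male")
#' @export
egfr_cr_cys <- function(creatinine, cystatin_c, age, sex,
                        params = egfr_params_2021()) {
  if (any(creatinine <= 0) || any(cystatin_c <= 0)) {
    stop("non-positive serum analyte value")
  }
  if (any(age <= 0) || any(age >= 120)) stop("age_at_draw outside (0, 120)")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (any(creatinine < 15)) {
    warning("creatinine value(s) < 15: input looks like mg/dL, but µmol/L is expected")
  }
  n <- max(length(creatinine), length(cystatin_c), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  cystatin_c <- rep_len(cystatin_c, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  scr <- creatinine / params$umol_per_mgdl
  kappa <- params$kappa[sex]
  alpha <- params$alpha[sex]
  r <- scr / kappa
  cys <- cystatin_c / params$cystatin_knot
  out <- params$scale *
    pmin(r, 1)^alpha * pmax(r, 1)^params$creatinine_high_exp *
    pmin(cys, 1)^params$cystatin_low_exp * pmax(cys, 1)^params$cystatin_high_exp *
    params$age_base^age
  out <- out * ifelse(sex == "female", params$female_multiplier, 1)
  unname(out)
}

#' Annual eGFR change from paired serum panels
#'
#' Merges baseline and follow-up serum panels per patient, computes eGFR at
#' each visit with the attained age, and derives the annual change as
#' (follow-up eGFR - baseline eGFR) / follow-up years. Negative values mean
#' more annual eGFR decline. Patients missing either timepoint are excluded
#' with a machine-readable reason, mirroring the cohort eligibility filter.
#'
#' @param panels long data frame, one row per patient-timepoint:
#'   `patient_id`, `timepoint` (`"baseline"`/`"followup"`), `creatinine`
#'   (µmol/L), `cystatin_c` (mg/L), `age_at_draw` (years), `sex`,
#'   `followup_years` (constant within patient; years between draws).
#' @param params equation constants, [egfr_params_2021()].
#' @return list with `kidney` (tibble: `patient_id`, `egfr_baseline`,
#'   `egfr_followup`, `followup_years`, `annual_change`, `ckd_baseline`) and
#'   `excluded` (tibble: `patient_id`, `reason`).
#' @export
annual_change <- function(panels, params = egfr_params_2021()) {
  panels <- as.data.frame(panels)
  need <- c("patient_id", "timepoint", "creatinine", "cystatin_c",
            "age_at_draw", "sex", "followup_years")
  stopifnot(all(need %in% names(panels)))
  if (!all(panels$timepoint %in% c("baseline", "followup"))) {
    stop("timepoint must be 'baseline' or 'followup'")
  }

  complete_serum <- !is.na(panels$creatinine) & !is.na(panels$cystatin_c)
  ids <- unique(panels$patient_id)
  has_base <- ids %in% panels$patient_id[panels$timepoint == "baseline" & complete_serum]
  has_fu <- ids %in% panels$patient_id[panels$timepoint == "followup" & complete_serum]
  ok <- has_base & has_fu
  excluded <- tibble::tibble(
    patient_id = ids[!ok],
    reason = ifelse(!has_base[!ok] & !has_fu[!ok], "missing_serum_both_timepoints",
                    ifelse(!has_base[!ok], "missing_serum_baseline",
                           "missing_serum_followup"))
  )

  keep <- panels[panels$patient_id %in% ids[ok] & complete_serum, , drop = FALSE]
  keep$egfr <- egfr_cr_cys(keep$creatinine, keep$cystatin_c,
                           keep$age_at_draw, keep$sex, params)
  base <- keep[keep$timepoint == "baseline", c("patient_id", "egfr", "followup_years")]
  fu <- keep[keep$timepoint == "followup", c("patient_id", "egfr")]
  names(base)[2] <- "egfr_baseline"
  names(fu)[2] <- "egfr_followup"
  kidney <- dplyr::inner_join(base, fu, by = "patient_id")
  if (any(kidney$followup_years <= 0)) stop("followup_years must be positive")
  kidney$annual_change <-
    (kidney$egfr_followup - kidney$egfr_baseline) / kidney$followup_years
  kidney$ckd_baseline <- flag_ckd(kidney$egfr_baseline)
  list(kidney = tibble::as_tibble(
         kidney[c("patient_id", "egfr_baseline", "egfr_followup",
                  "followup_years", "annual_change", "ckd_baseline")]),
       excluded = excluded)
}

#' Prevalent CKD flag
#'
#' Prevalent chronic kidney disease is defined as baseline
#' eGFR < 60 mL/min per 1.73 m² (strict).
#'
#' @param egfr_baseline baseline eGFR values.
#' @return logical vector.
#' @export
flag_ckd <- function(egfr_baseline) {
  if (any(!is.finite(egfr_baseline))) stop("non-finite eGFR")
  egfr_baseline < 60
}
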
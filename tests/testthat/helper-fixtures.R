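# Shared fixtures, built in code.

# A single intake record meeting every full-adherence condition.
perfect_intake <- function(patient_id = "P1", sex = "male") {
  tibble::tibble(
    patient_id = patient_id, sex = sex,
    vegetables = 250, fruit = 250, whole_grains = 150, refined_grains = 0,
    legumes = 15, nuts_unsalted = 20, nuts_total = 25, dairy = 350,
    fish = 25, tea = 500, liquid_fats = 25, solid_fats = 0,
    red_meat = 30, processed_meat = 0, ssb_juice = 0, alcohol = 5,
    sodium = 1500, sterol_products = 10, sterol_use = TRUE, energy = 2000
  )
}

# All intakes zero, no sterol use.
zero_intake <- function(patient_id = "P1", sex = "male") {
  x <- perfect_intake(patient_id, sex)
  num <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "energy")
  x[num] <- 0
  x$sterol_use <- FALSE
  x$energy <- 2000
  x
}

# Independent rule-by-rule evaluation of the default ruleset, written as a
# direct transcription of each component's shape (the brute-force oracle).
oracle_total_score <- function(r) {
  ramp_up <- function(x, hi) 10 * min(1, max(0, x / hi))
  ramp_down <- function(x, full, zero) {
    if (x <= full) 10 else 10 * min(1, max(0, (zero - x) / (zero - full)))
  }
  ratio_score <- function(num, den) if (den <= 0) 10 else 10 * min(1, num / den)
  dairy <- 10 * min(min(1, max(0, r$dairy / 300)),
                    min(1, max(0, (750 - r$dairy) / 300)))
  alcohol_zero <- if (r$sex == "female") 20 else 30
  ramp_up(r$vegetables, 200) + ramp_up(r$fruit, 200) +
    ratio_score(r$whole_grains, r$refined_grains) +
    ramp_up(r$legumes, 10) + ramp_up(r$nuts_unsalted, 15) + dairy +
    ramp_up(r$fish, 21) + ramp_up(r$tea, 450) +
    ratio_score(r$liquid_fats, r$solid_fats) +
    ramp_down(r$red_meat, 45, 100) + ramp_down(r$processed_meat, 0, 50) +
    ramp_down(r$ssb_juice, 0, 250) + ramp_down(r$alcohol, 10, alcohol_zero) +
    ramp_down(r$sodium, 1900, 3800) + 10 * as.numeric(r$sterol_use)
}

# Random intake table for property sweeps.
random_intakes <- function(n, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    vegetables = runif(n, 0, 400), fruit = runif(n, 0, 500),
    whole_grains = runif(n, 0, 300), refined_grains = runif(n, 0, 200),
    legumes = runif(n, 0, 40), nuts_unsalted = runif(n, 0, 40),
    nuts_total = runif(n, 0, 60), dairy = runif(n, 0, 1000),
    fish = runif(n, 0, 60), tea = runif(n, 0, 900),
    liquid_fats = runif(n, 0, 60), solid_fats = runif(n, 0, 60),
    red_meat = runif(n, 0, 150), processed_meat = runif(n, 0, 100),
    ssb_juice = runif(n, 0, 500), alcohol = runif(n, 0, 60),
    sodium = runif(n, 500, 5000), sterol_products = runif(n, 0, 30),
    energy = runif(n, 1200, 3200)
  ) |>
    dplyr::mutate(sterol_use = sterol_products > 0)
}

# Five-patient toy input for the eligibility-filter accounting check:
# one patient misses the follow-up serum panel, one man eats 700 kcal/day.
toy_pipeline_inputs <- function() {
  ids <- paste0("T", 1:5)
  intake <- dplyr::bind_rows(lapply(ids, perfect_intake))
  intake$patient_id <- ids
  intake$energy <- c(2000, 2100, 700, 2200, 1900)
  intake$fruit <- c(110, 150, 200, 90, 60)  # distinct diet scores
  serum <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids, timepoint = "baseline", creatinine = 84,
                   cystatin_c = 0.92, age_at_draw = 69, sex = "male",
                   followup_years = 40 / 12),
    tibble::tibble(patient_id = ids, timepoint = "followup", creatinine = 85,
                   cystatin_c = c(0.95, NA, 0.95, 0.95, 0.95),
                   age_at_draw = 69 + 40 / 12, sex = "male",
                   followup_years = 40 / 12))
  covariates <- tibble::tibble(
    patient_id = ids, sex = "male", age = 69,
    education = factor("low", levels = c("elementary", "low", "intermediate", "high")),
    smoking = factor("former", levels = c("never", "former", "current")),
    physical_activity = factor("low", levels = c("low", "intermediate", "high")),
    lipid_lowering = TRUE, raas = FALSE, diuretics = FALSE,
    loop_diuretics = FALSE, sbp = 143, bmi = 27, hdl = 1.2, glucose = 5.4,
    fasted_gt_4h = TRUE, diabetes_self_report = FALSE,
    glucose_lowering_med = FALSE, energy = intake$energy)
  list(intake = intake, serum = serum, covariates = covariates)
}
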
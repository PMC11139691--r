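#' Configuration of the synthetic cohort generator
#'
#' Returns the default generator configuration, an elderly post-MI cohort:
#' 19.2% women, age 68.9 +/- 5.4 years truncated to 60--80, skewed and
#' partly zero-inflated food-group intakes moment-matched to the cohort's
#' published medians and interquartile ranges, baseline eGFR around a median
#' of 87 mL/min per 1.73 m², follow-up drawn uniformly between 38 and 42
#' months, and a planted linear decline model
#' \deqn{\Delta = \beta_0 + \beta_{diet} z_{diet} + \beta_{grs} z_{grs} + \epsilon}
#' with intercept -1.71, residual SD 3.86 (mL/min per 1.73 m² per year) and
#' standardized diet-score and genetic-risk exposures. Intakes are drawn
#' independently per component except the two ratio components, whose
#' denominators (refined grains, solid fats) are derived from the numerator
#' through a log-ratio distribution calibrated to the published component
#' score quantiles.
#'
#' @param n_patients cohort size (>= 10).
#' @param beta_diet planted diet effect per 1-SD of total score (default
#'   -0.09).
#' @param beta_grs planted genetic effect per 1-SD of GRS_all (default
#'   -0.10).
#' @param decline_intercept mean annual eGFR change at average exposure
#'   (default -1.71).
#' @param residual_sd residual SD of annual change (default 3.86).
#' @param prop_female proportion of women (default 0.192).
#' @param include_genetics generate GWAS fixture, dosages and PCs.
#' @param n_snps total SNPs in the fixture (default 110: 16 genome-wide
#'   significant, 72 nominal-only, 10 palindromic, 12 non-significant).
#' @param missing_rates named covariate missingness rates; defaults follow
#'   the published per-covariate missing counts (about 0.1--0.8%).
#' @param missing_mechanism `"MCAR"` or `"MAR"` (MAR conditions on sex).
#' @param serum_missing_rate fraction of patients with a missing follow-up
#'   serum panel (default 0; used to exercise the eligibility filter).
#' @param diet_missing_rate fraction of patients with an incomplete intake
#'   record (default 0).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 2000,
                             beta_diet = -0.09,
                             beta_grs = -0.10,
                             decline_intercept = -1.71,
                             residual_sd = 3.86,
                             prop_female = 0.192,
                             include_genetics = TRUE,
                             n_snps = 110,
                             missing_rates = c(education = 0.005,
                                               physical_activity = 0.004,
                                               hdl = 0.005,
                                               sbp = 0.0014,
                                               bmi = 0.001,
                                               glucose = 0.008),
                             missing_mechanism = "MCAR",
                             serum_missing_rate = 0,
                             diet_missing_rate = 0) {
  stopifnot(n_patients >= 10, residual_sd > 0,
            prop_female >= 0, prop_female <= 1,
            all(missing_rates >= 0), all(missing_rates < 1),
            serum_missing_rate >= 0, serum_missing_rate < 1,
            n_snps >= 4)
  structure(
    list(n_patients = n_patients, beta_diet = beta_diet, beta_grs = beta_grs,
         decline_intercept = decline_intercept, residual_sd = residual_sd,
         prop_female = prop_female, include_genetics = include_genetics,
         n_snps = n_snps, missing_rates = missing_rates,
         missing_mechanism = missing_mechanism,
         serum_missing_rate = serum_missing_rate,
         diet_missing_rate = diet_missing_rate,
         age_mean = 68.9, age_sd = 5.4, age_range = c(60, 80),
         egfr_meanlog = log(87), egfr_sdlog = 0.246,
         followup_months = c(38, 42)),
    class = "synthetic_config")
}

rlnorm_trunc <- function(n, meanlog, sdlog, cap = Inf) {
  pmin(stats::rlnorm(n, meanlog, sdlog), cap)
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Zero-inflated lognormal: a point mass at zero plus a lognormal consumer
# distribution (food groups with non-consumers: legumes, nuts, fish, ...).
rziln <- function(n, p_zero, meanlog, sdlog, cap = Inf) {
  x <- rlnorm_trunc(n, meanlog, sdlog, cap)
  x[stats::runif(n) < p_zero] <- 0
  x
}

# Intake marginals moment-matched to the published cohort medians / IQRs.
generate_intakes <- function(n, sex) {
  whole_grains <- rlnorm_trunc(n, log(119.8), 0.446)
  grain_ratio <- stats::rlnorm(n, log(0.665), 0.374)
  liquid_fats <- rlnorm_trunc(n, log(21.7), 0.674)
  fat_ratio <- stats::rlnorm(n, log(0.145), 3.364)
  nuts_total <- rziln(n, 0.305, log(2.6), 1.017, cap = 120)
  sterol_products <- rziln(n, 1 - 0.404, log(13.5), 0.8, cap = 80)
  tibble::tibble(
    vegetables = rlnorm_trunc(n, log(85.3), 0.415, cap = 800),
    fruit = rlnorm_trunc(n, log(110), 1.30, cap = 1500),
    whole_grains = whole_grains,
    refined_grains = pmin(whole_grains / grain_ratio, 500),
    legumes = rziln(n, 0.477, log(6.2), 0.557, cap = 150),
    nuts_total = nuts_total,
    nuts_unsalted = nuts_total * stats::runif(n, 0.4, 0.9),
    dairy = rlnorm_trunc(n, log(301), 0.578, cap = 2000),
    fish = rziln(n, 0.187, log(13.6), 0.694, cap = 200),
    tea = rlnorm_trunc(n, log(150), 2.407, cap = 2000),
    liquid_fats = liquid_fats,
    solid_fats = pmin(liquid_fats / fat_ratio, 200),
    red_meat = rlnorm_trunc(n, log(37.1), 0.714, cap = 400),
    processed_meat = rlnorm_trunc(n, log(22.3), 0.907, cap = 400),
    ssb_juice = rlnorm_trunc(n, log(160.5), 0.927, cap = 2500),
    alcohol = rziln(n, 0.23, 2.45, 0.99, cap = 150),
    sodium = rnorm_trunc(n, 2222, 659, lo = 200),
    sterol_products = sterol_products,
    sterol_use = sterol_products > 0,
    energy = rlnorm_trunc(n, log(1875), 0.263, cap = 7000)
  )
}

#' Invert the eGFR equation for cystatin C
#'
#' Solves the 2021 CKD-EPI combined equation for the serum cystatin C value
#' that yields a target eGFR at given creatinine, age and sex. The cystatin
#' factor is a piecewise power law, monotone decreasing, so the inverse is
#' exact: the round-trip through [egfr_cr_cys()] recovers the target to
#' machine precision. Used by the generator so planted eGFR trajectories are
#' reproduced exactly by the kidney-function stage.
#'
#' @param target_egfr desired eGFR, mL/min per 1.73 m² (> 0).
#' @param creatinine serum creatinine, µmol/L.
#' @param age,sex as in [egfr_cr_cys()].
#' @param params equation constants.
#' @return cystatin C in mg/L.
#' @export
invert_egfr <- function(target_egfr, creatinine, age, sex,
                        params = egfr_params_2021()) {
  if (any(!is.finite(target_egfr)) || any(target_egfr <= 0)) {
    stop("target eGFR must be positive and finite")
  }
  sex <- as.character(sex)
  n <- max(length(target_egfr), length(creatinine), length(age), length(sex))
  target_egfr <- rep_len(target_egfr, n)
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  scr <- creatinine / params$umol_per_mgdl
  r <- scr / params$kappa[sex]
  const <- params$scale *
    pmin(r, 1)^params$alpha[sex] * pmax(r, 1)^params$creatinine_high_exp *
    params$age_base^age * ifelse(sex == "female", params$female_multiplier, 1)
  ratio <- target_egfr / const
  exp_used <- ifelse(ratio >= 1, params$cystatin_low_exp, params$cystatin_high_exp)
  unname(params$cystatin_knot * ratio^(1 / exp_used))
}

#' Inject missing values into covariates
#'
#' Masks covariate entries at configured per-column rates, either completely
#' at random (MCAR) or conditionally on sex (MAR: the rate is multiplied by
#' 1.5 for women and 0.5 for men). Outcome, exposure and identifier columns
#' are protected.
#'
#' @param covariates data frame (must contain `sex` for MAR).
#' @param rates named vector of per-column missingness rates in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed optional RNG seed.
#' @param protected columns that may never receive missingness.
#' @return list with `data` (masked tibble) and `mask` (logical tibble of
#'   the injected gaps, same shape as the affected columns).
#' @export
inject_missingness <- function(covariates, rates,
                               mechanism = c("MCAR", "MAR"),
                               seed = NULL,
                               protected = c("patient_id", "sex", "total",
                                             "annual_change")) {
  mechanism <- match.arg(mechanism)
  stopifnot(all(rates >= 0), all(rates < 1))
  hit <- intersect(names(rates), protected)
  if (length(hit) > 0) {
    stop("missingness requested on protected column(s): ", paste(hit, collapse = ", "))
  }
  missing_cols <- setdiff(names(rates), names(covariates))
  if (length(missing_cols) > 0) {
    stop("rate given for absent column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  covariates <- tibble::as_tibble(covariates)
  n <- nrow(covariates)
  mask <- matrix(FALSE, n, length(rates), dimnames = list(NULL, names(rates)))
  for (col in names(rates)) {
    p <- rep(rates[[col]], n)
    if (mechanism == "MAR") {
      p <- p * ifelse(as.character(covariates$sex) == "female", 1.5, 0.5)
    }
    m <- stats::runif(n) < p
    covariates[[col]][m] <- NA
    mask[, col] <- m
  }
  list(data = covariates, mask = tibble::as_tibble(as.data.frame(mask)))
}

#' Generate the GWAS fixture, dosage matrix and genetic PCs
#'
#' Builds a summary-statistics table whose p-values straddle both selection
#' thresholds -- by default 16 genome-wide significant (p < 5e-8) and 72
#' nominal-only non-ambiguous SNPs, 10 palindromic (A/T or C/G) SNPs and 12
#' non-significant SNPs -- plus a patient x SNP dosage matrix drawn from
#' Binomial(2, MAF) with small additive noise to mimic imputed dosages, and
#' three synthetic genetic principal components. Cohort allele orientation
#' is randomized per SNP (direct, dosage-flipped, or strand-complemented) so
#' every harmonization branch is exercised. The construction guarantees
#' non-empty main and sub SNP sets and at least one excluded ambiguous SNP.
#'
#' @param n_patients number of patients.
#' @param n_snps total SNPs (>= 4); partitioned 16/72/10/12 scaled to
#'   `n_snps`.
#' @param patient_ids optional ids for the dosage matrix rows.
#' @return list with `gwas` (tibble), `dosages` (`dosage_matrix` list),
#'   `pcs` (tibble pc1..pc3), and `truth` (per-SNP effect-allele dosage
#'   orientation and weights).
#' @export
generate_genetics <- function(n_patients, n_snps = 110, patient_ids = NULL) {
  stopifnot(n_snps >= 4)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%05d", seq_len(n_patients))
  counts <- round(n_snps * c(gw = 16, nom = 72, amb = 10, none = 12) / 110)
  counts[1] <- max(counts[1], 1)
  counts[3] <- max(counts[3], 1)
  counts[4] <- n_snps - sum(counts[1:3])
  group <- rep(names(counts), counts)
  n <- length(group)
  rsid <- sprintf("rs%06d", seq_len(n))

  nonpal <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                 c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pairs[[i]] <- if (group[i] == "amb") pal[[sample.int(4, 1)]] else
      nonpal[[sample.int(8, 1)]]
  }
  effect <- vapply(pairs, `[[`, character(1), 1)
  other <- vapply(pairs, `[[`, character(1), 2)
  p_value <- numeric(n)
  p_value[group == "gw"] <- 10^stats::runif(sum(group == "gw"), -20, -7.5)
  p_value[group == "nom"] <- 10^stats::runif(sum(group == "nom"), -6, -1.35)
  p_value[group == "amb"] <- 10^stats::runif(sum(group == "amb"), -10, -1.5)
  p_value[group == "none"] <- stats::runif(sum(group == "none"), 0.06, 0.9)
  weight <- stats::rnorm(n, 0, 0.08)
  gwas <- tibble::tibble(rsid = rsid, effect_allele = effect,
                         other_allele = other, weight = weight,
                         p_value = p_value)

  maf <- stats::runif(n, 0.05, 0.5)
  hard <- matrix(stats::rbinom(n_patients * n, 2, rep(maf, each = n_patients)),
                 nrow = n_patients)
  dos_effect <- hard + stats::rnorm(n_patients * n, 0, 0.05)
  dos_effect <- pmin(pmax(dos_effect, 0), 2)  # argument order keeps dim attributes

  # Randomize the cohort's reported orientation per SNP: the stored dosage
  # counts `counted_allele`, possibly the non-effect allele and/or on the
  # opposite strand (strand flips only for non-palindromic SNPs).
  comp <- BASE_COMPLEMENT
  orient <- sample(c("as_is", "flip_dosage", "strand_flip_as_is",
                     "strand_flip_dosage"), n, replace = TRUE)
  orient[group == "amb"] <- sample(c("as_is", "flip_dosage"),
                                   sum(group == "amb"), replace = TRUE)
  counted <- character(n)
  observed_other <- character(n)
  stored <- dos_effect
  for (i in seq_len(n)) {
    ea <- effect[i]; oa <- other[i]
    switch(orient[i],
      as_is = { counted[i] <- ea; observed_other[i] <- oa },
      flip_dosage = {
        counted[i] <- oa; observed_other[i] <- ea
        stored[, i] <- 2 - dos_effect[, i]
      },
      strand_flip_as_is = {
        counted[i] <- comp[ea]; observed_other[i] <- comp[oa]
      },
      strand_flip_dosage = {
        counted[i] <- comp[oa]; observed_other[i] <- comp[ea]
        stored[, i] <- 2 - dos_effect[, i]
      })
  }
  dimnames(stored) <- list(patient_ids, rsid)
  dosages <- list(dosages = stored,
                  counted_allele = stats::setNames(counted, rsid),
                  other_allele = stats::setNames(observed_other, rsid))
  pcs <- tibble::tibble(patient_id = patient_ids,
                        pc1 = stats::rnorm(n_patients),
                        pc2 = stats::rnorm(n_patients),
                        pc3 = stats::rnorm(n_patients))
  truth <- list(effect_dosages = `dimnames<-`(dos_effect, list(patient_ids, rsid)),
                gwas_group = stats::setNames(group, rsid),
                maf = stats::setNames(maf, rsid),
                orientation = stats::setNames(orient, rsid))
  list(gwas = gwas, dosages = dosages, pcs = pcs, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Draws a full set of pipeline inputs -- intake table, paired serum panels,
#' covariates with injected missingness, genotype dosages with a GWAS
#' summary-statistics fixture -- from a planted eGFR-decline model, and
#' returns them together with the ground truth needed for recovery tests.
#' Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return list with `intake`, `serum` (long per patient-timepoint),
#'   `covariates`, `genetics` (`NULL` unless configured), and `truth`
#'   (planted betas, standardized exposures, true annual change,
#'   missingness mask).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_patients
  patient_id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  age <- rnorm_trunc(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])

  intake <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id, sex = sex, age = age),
    generate_intakes(n, sex))

  scores <- score_index(intake)
  z_diet <- as.numeric(scale(scores$total))

  genetics <- NULL
  z_grs <- rep(0, n)
  if (config$include_genetics) {
    genetics <- generate_genetics(n, config$n_snps, patient_id)
    sel_truth <- genetics$truth$gwas_group %in% c("gw", "nom")
    w <- genetics$gwas$weight[sel_truth]
    grs_true <- drop(genetics$truth$effect_dosages[, sel_truth, drop = FALSE] %*% w)
    z_grs <- as.numeric(scale(grs_true))
  }

  eps <- stats::rnorm(n, 0, config$residual_sd)
  annual_true <- config$decline_intercept +
    config$beta_diet * z_diet + config$beta_grs * z_grs + eps

  followup_years <- stats::runif(n, config$followup_months[1],
                                 config$followup_months[2]) / 12
  egfr_base <- pmin(pmax(stats::rlnorm(n, config$egfr_meanlog, config$egfr_sdlog),
                         20), 140)
  egfr_fu <- pmax(egfr_base + annual_true * followup_years, 5)
  annual_true <- (egfr_fu - egfr_base) / followup_years  # after flooring

  creat_meanlog <- ifelse(sex == "female", log(70), log(88))
  creat_base <- pmin(pmax(stats::rlnorm(n, creat_meanlog, 0.17), 30), 400)
  creat_fu <- pmin(pmax(creat_base * stats::rlnorm(n, 0, 0.05), 30), 400)
  age_fu <- age + followup_years
  cys_base <- invert_egfr(egfr_base, creat_base, age, sex)
  cys_fu <- invert_egfr(egfr_fu, creat_fu, age_fu, sex)

  serum <- dplyr::bind_rows(
    tibble::tibble(patient_id = patient_id, timepoint = "baseline",
                   creatinine = creat_base, cystatin_c = cys_base,
                   age_at_draw = age, sex = sex,
                   followup_years = followup_years),
    tibble::tibble(patient_id = patient_id, timepoint = "followup",
                   creatinine = creat_fu, cystatin_c = cys_fu,
                   age_at_draw = age_fu, sex = sex,
                   followup_years = followup_years))

  if (config$serum_missing_rate > 0) {
    drop_fu <- stats::runif(n) < config$serum_missing_rate
    serum$cystatin_c[serum$timepoint == "followup"][drop_fu] <- NA
  }
  if (config$diet_missing_rate > 0) {
    drop_diet <- stats::runif(n) < config$diet_missing_rate
    intake$vegetables[drop_diet] <- NA
  }

  education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                      prob = c(0.207, 0.361, 0.311, 0.122))
  smoking <- sample(SMOKING_LEVELS, n, replace = TRUE,
                    prob = c(0.166, 0.683, 0.151))
  physical_activity <- sample(ACTIVITY_LEVELS, n, replace = TRUE,
                              prob = c(0.396, 0.374, 0.230))
  covariates <- tibble::tibble(
    patient_id = patient_id, sex = sex, age = age,
    education = factor(education, EDUCATION_LEVELS),
    smoking = factor(smoking, SMOKING_LEVELS),
    physical_activity = factor(physical_activity, ACTIVITY_LEVELS),
    lipid_lowering = stats::runif(n) < 0.863,
    raas = stats::runif(n) < 0.52,
    diuretics = stats::runif(n) < 0.204,
    loop_diuretics = stats::runif(n) < 0.06,
    sbp = rnorm_trunc(n, 143, 21.2, lo = 70),
    bmi = rnorm_trunc(n, 27.6, 3.61, lo = 15, hi = 55),
    hdl = stats::rlnorm(n, log(1.21), 0.243),
    glucose = stats::rlnorm(n, log(5.46), 0.183),
    fasted_gt_4h = stats::runif(n) < 0.5,
    diabetes_self_report = stats::runif(n) < 0.10,
    glucose_lowering_med = stats::runif(n) < 0.14,
    energy = intake$energy
  )
  covariates <- derive_flags(covariates)
  if (config$include_genetics) {
    covariates <- dplyr::left_join(covariates, genetics$pcs, by = "patient_id")
  }

  mask <- NULL
  if (length(config$missing_rates) > 0 && any(config$missing_rates > 0)) {
    inj <- inject_missingness(covariates, config$missing_rates,
                              mechanism = config$missing_mechanism)
    covariates <- inj$data
    mask <- inj$mask
  }

  truth <- list(
    beta_diet = config$beta_diet, beta_grs = config$beta_grs,
    decline_intercept = config$decline_intercept,
    residual_sd = config$residual_sd,
    z_diet = z_diet, z_grs = z_grs,
    total_score = scores$total,
    annual_change = annual_true,
    egfr_baseline = egfr_base, egfr_followup = egfr_fu,
    missingness_mask = mask,
    seed = seed)

  list(intake = intake, serum = serum, covariates = covariates,
       genetics = genetics, truth = truth, config = config)
}
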
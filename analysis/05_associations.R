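#!/usr/bin/env Rscript
# Association models: assemble the analysis table, impute incomplete
# covariates (chained equations, 10 imputations x 10 iterations), and fit
# the model suite -- total index per 1-SD under M1/M2/M3, tertile contrasts
# with a trend test, per-component models, subgroup reruns, and
# GRS-stratified models.

suppressPackageStartupMessages({
  library(dhdkidney)
  library(dplyr)
})

scores <- utils::read.delim("results/scores.tsv") |>
  mutate(tertile = factor(tertile, c("T1", "T2", "T3")))
kidney <- utils::read.delim("results/kidney.tsv")
grs <- utils::read.delim("results/grs.tsv") |>
  mutate(stratum_all = factor(stratum_all, c("T1", "T2", "T3")),
         stratum_sub = factor(stratum_sub, c("low", "high")))
covs <- utils::read.delim("results/cohort/covariates.tsv") |>
  mutate(education = factor(education, c("elementary", "low", "intermediate", "high")),
         smoking = factor(smoking, c("never", "former", "current")),
         physical_activity = factor(physical_activity, c("low", "intermediate", "high")))

analysis <- scores |>
  inner_join(kidney[c("patient_id", "annual_change", "ckd_baseline")],
             by = "patient_id") |>
  inner_join(select(covs, -sex), by = "patient_id") |>
  left_join(grs, by = "patient_id")
cat(sprintf("Analysis table: %d patients, %d with genetic data\n",
            nrow(analysis), sum(!is.na(analysis$grs_all))))

fit_cols <- unique(c("patient_id", "annual_change", "total", "tertile",
                     model_covariates("M3"), "ckd_baseline", "obesity",
                     grep("^score_", names(analysis), value = TRUE)))
imp <- mice_impute(analysis[fit_cols], m = 10, maxit = 10, seed = 2,
                   must_be_complete = c("annual_change", "total"))
cat(sprintf("Imputed columns: %s\n",
            paste(attr(imp, "imputed_columns"), collapse = ", ")))

# Main model suite: total index per 1-SD, with subgroup reruns.
main <- run_model_suite(imp,
                        subgroups = list(diabetes = "diabetes",
                                         obesity = "obesity",
                                         ckd = "ckd_baseline"))
cat("\nTotal DHD-CVD index per 1-SD increment vs annual eGFR change:\n")
for (i in which(main$subgroup == "all")) {
  cat(sprintf("  %-3s %s\n", main$model[i],
              format_beta(main$beta[i], main$ci_low[i], main$ci_high[i])))
}

# Tertile contrasts under the main model (M2) with a trend test.
tert <- tertile_model(imp[[1]], "annual_change", "tertile", model_covariates("M2"))
cat("\nSex-specific tertiles (T1 reference, M2, first imputation):\n")
for (i in seq_len(nrow(tert$estimates))) {
  cat(sprintf("  %s %s\n", tert$estimates$term[i],
              format_beta(tert$estimates$beta[i], tert$estimates$ci_low[i],
                          tert$estimates$ci_high[i])))
}
cat(sprintf("  P_trend = %.2f\n", tert$p_trend))

# Per-component adherence scores (M2 plus all other components).
score_cols <- grep("^score_", names(analysis), value = TRUE)
comp_specs <- lapply(score_cols, function(cn) {
  list(name = sub("^score_", "", cn), column = cn, type = "per_sd_increment")
})
components <- run_model_suite(imp, exposures = comp_specs,
                              models = "component_M2",
                              other_components = score_cols)

# GRS-stratified main model (M2 plus genetic PCs) among complete genetic data.
gen <- analysis[!is.na(analysis$grs_all), ]
gen_cc <- gen[stats::complete.cases(gen[c(model_covariates("genetic_M2"),
                                          "annual_change", "total")]), ]
genetic <- run_model_suite(gen_cc, models = "genetic_M2",
                           subgroups = list(grs_all = "stratum_all",
                                            grs_sub = "stratum_sub"))
cat("\nTotal index per 1-SD within genetic risk strata (M2 + 3 PCs):\n")
for (i in seq_len(nrow(genetic))) {
  cat(sprintf("  %-14s n=%-5d %s\n", genetic$subgroup[i], genetic$n[i],
              format_beta(genetic$beta[i], genetic$ci_low[i], genetic$ci_high[i])))
}

results <- bind_rows(main = main, components = components, genetic = genetic,
                     .id = "suite")
utils::write.table(as.data.frame(results), "results/associations.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(data.frame(term = tert$estimates$term,
                              beta = tert$estimates$beta,
                              ci_low = tert$estimates$ci_low,
                              ci_high = tert$estimates$ci_high,
                              p_trend = tert$p_trend),
                   "results/tertile_contrasts.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
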
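#!/usr/bin/env Rscript
# Generate the synthetic analysis cohort (2169 patients, the analytical
# sample size of the study design this pipeline emulates) and write the raw
# input tables. Downstream scripts consume only these files.

suppressPackageStartupMessages(library(dhdkidney))

seed <- 1
cfg <- synthetic_config(n_patients = 2169)
coh <- generate_cohort(cfg, seed = seed)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
wt <- function(x, f) utils::write.table(as.data.frame(x),
                                        file.path("results/cohort", f),
                                        sep = "\t", row.names = FALSE, quote = FALSE)
wt(coh$intake, "intake.tsv")
wt(coh$serum, "serum.tsv")
wt(coh$covariates, "covariates.tsv")
wt(coh$genetics$gwas, "gwas.tsv")
dos <- data.frame(patient_id = rownames(coh$genetics$dosages$dosages),
                  coh$genetics$dosages$dosages, check.names = FALSE)
wt(dos, "dosages.tsv")
wt(data.frame(rsid = names(coh$genetics$dosages$counted_allele),
              counted_allele = coh$genetics$dosages$counted_allele,
              other_allele = coh$genetics$dosages$other_allele),
   "dosage_alleles.tsv")
wt(data.frame(patient_id = coh$intake$patient_id,
              annual_change_true = coh$truth$annual_change,
              z_diet = coh$truth$z_diet, z_grs = coh$truth$z_grs),
   "truth.tsv")
yaml::write_yaml(list(seed = seed, n_patients = cfg$n_patients,
                      beta_diet = cfg$beta_diet, beta_grs = cfg$beta_grs,
                      residual_sd = cfg$residual_sd),
                 "results/cohort/manifest.yaml")

cat(sprintf("Simulated %d patients (%.1f%% women, age %.1f +/- %.1f y)\n",
            nrow(coh$intake), 100 * mean(coh$intake$sex == "female"),
            mean(coh$covariates$age), sd(coh$covariates$age)))
cat(sprintf("Planted decline model: %.2f %+.2f z_diet %+.2f z_grs, residual SD %.2f\n",
            cfg$decline_intercept, cfg$beta_diet, cfg$beta_grs, cfg$residual_sd))
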
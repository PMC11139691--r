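#!/usr/bin/env Rscript
# Non-linearity check: sex-stratified restricted cubic splines (3 knots at
# the 10th/50th/90th percentiles) of the total index vs annual eGFR change,
# referenced to the median of the bottom tertile within each sex.

suppressPackageStartupMessages({
  library(dhdkidney)
  library(dplyr)
})

scores <- utils::read.delim("results/scores.tsv") |>
  mutate(tertile = factor(tertile, c("T1", "T2", "T3")))
kidney <- utils::read.delim("results/kidney.tsv")
covs <- utils::read.delim("results/cohort/covariates.tsv") |>
  mutate(education = factor(education, c("elementary", "low", "intermediate", "high")),
         smoking = factor(smoking, c("never", "former", "current")),
         physical_activity = factor(physical_activity, c("low", "intermediate", "high")))

analysis <- scores |>
  inner_join(kidney[c("patient_id", "annual_change")], by = "patient_id") |>
  inner_join(select(covs, -sex), by = "patient_id")

covariates <- setdiff(model_covariates("M2"), "sex")
curves <- lapply(c("female", "male"), function(s) {
  d <- analysis[analysis$sex == s, ]
  d <- d[stats::complete.cases(d[c(covariates, "annual_change", "total")]), ]
  ref <- median(d$total[d$tertile == "T1"])
  cur <- spline_curve(d, "annual_change", "total", covariates, ref = ref)
  cat(sprintf("%s: n=%d, reference score %.0f, knots %.1f / %.1f / %.1f\n",
              s, nrow(d), ref, attr(cur, "knots")[1], attr(cur, "knots")[2],
              attr(cur, "knots")[3]))
  cur$sex <- s
  cur$reference <- ref
  cur
})
curves <- bind_rows(curves)

utils::write.table(as.data.frame(curves), "results/spline_curves.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("Wrote results/spline_curves.tsv (one row per evaluation point per sex)\n")
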
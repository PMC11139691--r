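# dhdkidney

Diet-quality scoring and kidney-function-decline analysis for
cardiovascular patient cohorts.

Patients with cardiovascular disease lose kidney function faster than the
general population, and whether adherence to food-based dietary guidelines
slows that loss — and whether genetic predisposition to chronic kidney
disease (CKD) modifies it — is an open epidemiological question. This
package provides a tested, reusable implementation of the full analysis
pipeline such a study needs, for epidemiologists and biostatisticians
working with cohort data of this shape (or wanting to prototype against
synthetic data of the same structure):

* **Diet scoring** — the DHD-CVD index: 15 guideline components
  (adequacy ramps, moderation ramps, an optimum range, two-input ratios,
  one binary), 0–10 points each, total 0–150; sex-specific energy
  plausibility filters; sex-specific tertiles; consumer flags. Component
  rules are declarative and configurable via a shipped YAML ruleset.
* **Kidney function** — eGFR from the race-free 2021 CKD-EPI combined
  creatinine–cystatin C equation

  eGFR = 135 · min(Scr/κ, 1)^α · max(Scr/κ, 1)^−0.544 ·
  min(Scys/0.8, 1)^−0.323 · max(Scys/0.8, 1)^−0.778 · 0.9961^age ·
  1.08[female],

  (κ = 0.7/0.9, α = −0.219/−0.144 for women/men), annual change
  Δ = (eGFR_followup − eGFR_baseline)/years, prevalent CKD at eGFR < 60.
* **Genetic risk** — weighted risk scores Σⱼ wⱼ·dᵢⱼ from GWAS
  summary statistics and imputed dosages, with risk-direction weight
  orientation, palindromic-SNP exclusion, strand-aware allele
  harmonization, p < 0.05 and p < 5e-8 SNP sets, tertile and median-split
  strata.
* **Association models** — OLS suites M1/M2/M3 (nested a-priori
  adjustment sets), per-1-SD exposure scaling with direction control,
  tertile contrasts with trend tests, restricted cubic splines (3 knots at
  the 10th/50th/90th percentiles), chained-equation multiple imputation
  (10 × 10) with Rubin's-rules pooling, and subgroup/GRS-stratified
  reruns.
* **Synthetic cohorts** — a generator with a planted decline model
  Δ = β₀ + β_diet·z_diet + β_grs·z_grs + ε (β₀ = −1.71, residual
  SD = 3.86) and marginals matched to a published elderly post-MI cohort,
  so the whole pipeline runs and calibrates without patient data.

## Worked example

```r
library(dhdkidney)

rules <- dhd_cvd_ruleset()
score_component(data.frame(fruit = 110), rules$fruit)
#> [1] 5.5
egfr_cr_cys(84, 0.92, 69, "male")   # µmol/L, mg/L, years
#> [1] 89.79191

run <- run_pipeline(config = synthetic_config(n_patients = 500), seed = 42)
report_pipeline(run)
#> Diet quality and annual eGFR change
#>
#>   dhd_total    M1   all            n=500   0.07 (-0.27,0.41)
#>   dhd_total    M2   all            n=500   0.09 (-0.25,0.43)
#>   dhd_total    M3   all            n=500   0.08 (-0.26,0.42)
#>
#> Patients analyzed: 500 of 500 (0 excluded)
```

The fruit component ramps linearly from 0 points at 0 g/d to 10 at
200 g/d, so a median intake of 110 g/d scores 5.5. The eGFR call evaluates
the 2021 combined equation for a 69-year-old man with creatinine
84 µmol/L and cystatin C 0.92 mg/L. The pipeline call generates a
500-patient synthetic cohort, applies the eligibility filters, scores
diet, computes annual eGFR change, builds genetic risk scores, imputes
incomplete covariates, and fits the three adjustment models for the total
score per 1-SD; betas are in mL/min per 1.73 m² per year, printed with
95% CIs. With the default planted effect of −0.09 per 1-SD a cohort of 500
is (correctly) too small to distinguish it from zero.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `06_splines.R`) writing tidy tables under
`results/`.

## The methods vignette

`vignettes/diet-kidney-methods.Rmd` documents the scoring shapes and their
default thresholds, the eGFR equation constants, harmonization
conventions, the imputation and pooling algorithms, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
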
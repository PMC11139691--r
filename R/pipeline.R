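#' Format an effect estimate the way the cohort tables print it
#'
#' Two decimals, `"beta (low,high)"`, e.g. `"-0.09 (-0.26,0.08)"`.
#'
#' @param beta,ci_low,ci_high numeric vectors.
#' @return character vector.
#' @export
format_beta <- function(beta, ci_low, ci_high) {
  sprintf("%.2f (%.2f,%.2f)", beta, ci_low, ci_high)
}

# Intake columns that constitute "complete dietary data".
INTAKE_COLUMNS <- c("vegetables", "fruit", "whole_grains", "refined_grains",
                    "legumes", "nuts_unsalted", "nuts_total", "dairy", "fish",
                    "tea", "liquid_fats", "solid_fats", "red_meat",
                    "processed_meat", "ssb_juice", "alcohol", "sodium",
                    "sterol_products", "energy")

#' Run the diet--kidney pipeline end to end
#'
#' Orchestrates the full analysis: eligibility exclusions in the cohort's
#' order (missing serum panels, incomplete dietary data, implausible energy
#' intake), DHD-CVD scoring with sex-specific tertiles, eGFR and annual
#' change, genetic risk scores, covariate imputation, and the model suite.
#' Exclusion counts always sum to the input n; nothing is dropped silently.
#'
#' @param inputs list with `intake`, `serum`, `covariates` and optionally
#'   `genetics` (as produced by [generate_cohort()], or read from delimited
#'   files with the same columns). Exactly one of `inputs` and `config`
#'   must be given.
#' @param config a [synthetic_config()]; the cohort is generated with
#'   `seed`.
#' @param seed RNG seed for generation and imputation.
#' @param ruleset component ruleset (default [dhd_cvd_ruleset()]).
#' @param models model ids to fit for the total-score exposure; `NULL` runs
#'   only the data stages (scoring, kidney, GRS, exclusions).
#' @param impute run chained-equation imputation on incomplete covariates
#'   (`m` = 10, `maxit` = 10); if `FALSE`, complete cases are used.
#' @param m,maxit imputation count and iterations.
#' @return list with `scores`, `kidney`, `grs`, `analysis` (merged table),
#'   `results` (tidy suite output), `tertile_results`, `exclusions`
#'   (tibble: patient_id, step, reason), `manifest`.
#' @export
run_pipeline <- function(inputs = NULL, config = NULL, seed = 1,
                         ruleset = dhd_cvd_ruleset(),
                         models = c("M1", "M2", "M3"),
                         impute = TRUE, m = 10, maxit = 10) {
  if (is.null(inputs) == is.null(config)) {
    stop("supply exactly one of `inputs` (real tables) or `config` (synthetic mode)")
  }
  if (!is.null(config)) inputs <- generate_cohort(config, seed = seed)

  intake <- tibble::as_tibble(inputs$intake)
  serum <- tibble::as_tibble(inputs$serum)
  n_input <- nrow(intake)
  exclusions <- list()

  # 1. serum eligibility: both panels with creatinine and cystatin C
  kid <- annual_change(serum)
  if (nrow(kid$excluded) > 0) {
    exclusions[[1]] <- tibble::tibble(patient_id = kid$excluded$patient_id,
                                      step = "serum", reason = kid$excluded$reason)
  }
  keep_ids <- intersect(intake$patient_id, kid$kidney$patient_id)
  intake1 <- intake[intake$patient_id %in% keep_ids, , drop = FALSE]

  # 2. incomplete dietary data
  diet_cols <- intersect(INTAKE_COLUMNS, names(intake1))
  incomplete <- !stats::complete.cases(intake1[diet_cols])
  if (any(incomplete)) {
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      patient_id = intake1$patient_id[incomplete],
      step = "diet", reason = "incomplete_dietary_data")
  }
  intake2 <- intake1[!incomplete, , drop = FALSE]

  # 3. implausible energy intake
  pf <- apply_plausibility_filter(intake2)
  if (nrow(pf$excluded) > 0) {
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      patient_id = pf$excluded$patient_id, step = "energy",
      reason = pf$excluded$reason)
  }
  analysis_intake <- pf$kept
  exclusions <- if (length(exclusions)) dplyr::bind_rows(exclusions) else
    tibble::tibble(patient_id = character(), step = character(), reason = character())
  stopifnot(nrow(analysis_intake) + nrow(exclusions) == n_input)

  scores <- score_index(analysis_intake, ruleset)
  scores <- assign_sex_specific_tertiles(scores)
  flags <- derive_consumer_flags(analysis_intake)
  kidney <- kid$kidney[kid$kidney$patient_id %in% analysis_intake$patient_id, ]

  grs <- NULL
  if (!is.null(inputs$genetics)) {
    gb <- build_grs(inputs$genetics$dosages, inputs$genetics$gwas)
    grs <- gb$grs[gb$grs$patient_id %in% analysis_intake$patient_id, ]
  }

  analysis <- scores |>
    dplyr::inner_join(kidney, by = "patient_id") |>
    dplyr::inner_join(dplyr::select(inputs$covariates, -dplyr::any_of(c("sex", "age"))),
                      by = "patient_id") |>
    dplyr::inner_join(dplyr::select(inputs$covariates, "patient_id", "age"),
                      by = "patient_id") |>
    dplyr::left_join(flags, by = "patient_id")
  if (!is.null(grs)) analysis <- dplyr::left_join(analysis, grs, by = "patient_id")

  results <- NULL
  tert <- NULL
  if (!is.null(models) && length(models) > 0) {
    needed <- unique(c("annual_change", "total", model_covariates("M3")))
    fit_data <- analysis[unique(c("patient_id", intersect(needed, names(analysis)),
                                  "tertile"))]
    if (impute && anyNA(fit_data)) {
      fit_list <- mice_impute(fit_data, m = m, maxit = maxit, seed = seed + 1,
                              must_be_complete = c("annual_change", "total"))
    } else {
      fit_list <- list(fit_data[stats::complete.cases(fit_data), , drop = FALSE])
    }
    results <- run_model_suite(fit_list, models = models)
    tert <- tertile_model(fit_list[[1]], "annual_change", "tertile",
                          model_covariates("M2"))
  }

  manifest <- list(seed = seed, n_input = n_input,
                   n_analyzed = nrow(analysis_intake),
                   n_excluded = nrow(exclusions),
                   models = models, impute = impute, m = m, maxit = maxit,
                   package_version = as.character(utils::packageVersion("dhdkidney")),
                   timestamp = format(Sys.time(), tz = "UTC"))

  list(scores = scores, kidney = kidney, grs = grs, analysis = analysis,
       results = results, tertile_results = tert,
       exclusions = exclusions, manifest = manifest)
}

#' Human-readable summary of pipeline results
#'
#' Prints the model-suite estimates in the cohort's display convention
#' (betas as `"b (l,u)"` with two decimals) plus the exclusion accounting.
#'
#' @param run output of [run_pipeline()].
#' @return character vector of report lines, invisibly; printed as a side
#'   effect.
#' @export
report_pipeline <- function(run) {
  lines <- c("Diet quality and annual eGFR change", "")
  res <- run$results
  if (is.null(res)) res <- tibble::tibble()
  for (i in seq_len(nrow(res))) {
    lines <- c(lines, sprintf("  %-12s %-4s %-14s n=%-5d %s",
                              res$exposure[i], res$model[i], res$subgroup[i],
                              res$n[i],
                              format_beta(res$beta[i], res$ci_low[i], res$ci_high[i])))
  }
  skipped <- attr(res, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0) {
    lines <- c(lines, sprintf("  %s: skipped (n < minimum)", skipped$subgroup))
  }
  lines <- c(lines, "",
             sprintf("Patients analyzed: %d of %d (%d excluded)",
                     run$manifest$n_analyzed, run$manifest$n_input,
                     run$manifest$n_excluded))
  if (nrow(run$exclusions) > 0) {
    tab <- table(run$exclusions$reason)
    lines <- c(lines, sprintf("  %s: %d", names(tab), as.integer(tab)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write pipeline outputs as delimited text
#'
#' Writes the score, kidney, GRS, results and exclusion tables plus a YAML
#' manifest into a directory.
#'
#' @param run output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wt(run$scores, "scores.tsv")
  wt(run$kidney, "kidney.tsv")
  wt(run$grs, "grs.tsv")
  wt(run$results, "results.tsv")
  wt(run$exclusions, "exclusions.tsv")
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
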
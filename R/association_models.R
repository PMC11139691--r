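EDUCATION_LEVELS <- c("elementary", "low", "intermediate", "high")
SMOKING_LEVELS <- c("never", "former", "current")
ACTIVITY_LEVELS <- c("low", "intermediate", "high")

#' Derive obesity and diabetes flags from raw covariates
#'
#' Obesity is BMI >= 30 kg/m² (inclusive). Diabetes mellitus is present in
#' case of a self-reported diagnosis, use of glucose-lowering medication, or
#' elevated plasma glucose: >= 7.0 mmol/L if fasted more than 4 h, or
#' >= 11.0 mmol/L if not fasted. Categorical covariates are validated
#' against their declared domains; missing inputs propagate to missing
#' flags.
#'
#' @param covariates data frame with `bmi`, `glucose`, `fasted_gt_4h`,
#'   `diabetes_self_report`, `glucose_lowering_med`, and (if present)
#'   `education`, `smoking`, `physical_activity` as factors/characters.
#' @return the data frame with logical `obesity` and `diabetes` columns
#'   added and categorical columns converted to factors with the canonical
#'   level order.
#' @export
derive_flags <- function(covariates) {
  cov <- tibble::as_tibble(covariates)
  check_domain <- function(col, levels) {
    if (col %in% names(cov)) {
      vals <- as.character(cov[[col]])
      bad <- setdiff(vals[!is.na(vals)], levels)
      if (length(bad) > 0) {
        stop("out-of-domain value(s) in ", col, ": ", paste(unique(bad), collapse = ", "))
      }
      cov[[col]] <<- factor(vals, levels = levels)
    }
  }
  check_domain("education", EDUCATION_LEVELS)
  check_domain("smoking", SMOKING_LEVELS)
  check_domain("physical_activity", ACTIVITY_LEVELS)

  cov$obesity <- cov$bmi >= 30
  glucose_rule <- ifelse(cov$fasted_gt_4h, cov$glucose >= 7.0, cov$glucose >= 11.0)
  cov$diabetes <- cov$diabetes_self_report | cov$glucose_lowering_med | glucose_rule
  # definite TRUE from one criterion overrides NA in another
  definite <- rowSums(cbind(cov$diabetes_self_report, cov$glucose_lowering_med,
                            glucose_rule), na.rm = TRUE) > 0
  cov$diabetes[definite] <- TRUE
  cov
}

#' Standardize an exposure to per-1-SD units
#'
#' `increment` maps x to (x - mean)/sd; `decrease` maps x to (mean - x)/sd,
#' so that a positive regression coefficient always points in the
#' guideline-concordant direction (e.g. "per 1-SD decrease in red meat
#' intake"). The SD is computed on the analysis sample.
#'
#' @param x numeric exposure values.
#' @param direction `"increment"` or `"decrease"`.
#' @return scaled vector with attributes `"sd"` and `"mean"`.
#' @export
standardize_exposure <- function(x, direction = c("increment", "decrease")) {
  direction <- match.arg(direction)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("exposure has zero variance; cannot scale per 1-SD")
  m <- mean(x)
  out <- if (direction == "increment") (x - m) / s else (m - x) / s
  attr(out, "sd") <- s
  attr(out, "mean") <- m
  out
}

#' Multivariable linear regression with tidy output
#'
#' Ordinary least squares via [stats::lm()] with closed-form coefficient
#' variances; 95% CIs use the t distribution with n - p degrees of freedom.
#' A rank-deficient design is an error naming the collinear columns.
#'
#' @param data analysis data frame.
#' @param outcome outcome column name (annual eGFR change in the main
#'   analysis).
#' @param terms character vector of right-hand-side column names.
#' @return tibble: `term`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `n`,
#'   `df`; attribute `"fit"` holds the `lm` object.
#' @export
fit_linear <- function(data, outcome, terms) {
  f <- stats::reformulate(terms, response = outcome)
  dat <- stats::model.frame(f, data = data)
  fit <- stats::lm(f, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  dfres <- fit$df.residual
  crit <- stats::qt(0.975, dfres)
  out <- tibble::tibble(
    term = rownames(co),
    beta = unname(co[, 1]),
    se = unname(co[, 2]),
    ci_low = unname(co[, 1] - crit * co[, 2]),
    ci_high = unname(co[, 1] + crit * co[, 2]),
    p = unname(co[, 4]),
    n = nrow(dat),
    df = dfres
  )
  attr(out, "fit") <- fit
  out
}

#' Tertile contrasts with a trend test
#'
#' Fits the outcome on tertile indicator contrasts (T1 as reference) plus
#' covariates, and obtains a p-for-trend from the same model refit with the
#' tertile entered as a single integer-coded (1, 2, 3) regressor. The
#' within-tertile-median coding is available as an alternative.
#'
#' @param data analysis data frame.
#' @param outcome outcome column name.
#' @param tertile name of a 3-level factor column (levels T1 < T2 < T3).
#' @param covariates character vector of adjustment columns.
#' @param trend_coding `"integer"` (default) or `"median"`; median coding
#'   replaces each tertile by the within-tertile median of `trend_on`.
#' @param trend_on column used for median coding (defaults to the outcome's
#'   exposure is unknown here, so it must be supplied when
#'   `trend_coding = "median"`).
#' @return list with `estimates` (tibble of T2, T3 contrasts) and `p_trend`.
#' @export
tertile_model <- function(data, outcome, tertile, covariates = character(),
                          trend_coding = c("integer", "median"),
                          trend_on = NULL) {
  trend_coding <- match.arg(trend_coding)
  tt <- data[[tertile]]
  if (!is.factor(tt)) stop("tertile column must be a factor")
  if (any(table(tt) == 0)) stop("empty tertile stratum")
  est <- fit_linear(data, outcome, c(tertile, covariates))
  keep <- grepl(paste0("^", tertile), est$term)
  estimates <- est[keep, , drop = FALSE]
  estimates$term <- sub(paste0("^", tertile), "", estimates$term)

  data$.trend <- if (trend_coding == "integer") {
    as.integer(tt)
  } else {
    if (is.null(trend_on)) stop("median trend coding requires trend_on")
    stats::ave(data[[trend_on]], tt, FUN = stats::median)[seq_len(nrow(data))]
  }
  tr <- fit_linear(data, outcome, c(".trend", covariates))
  list(estimates = estimates, p_trend = tr$p[tr$term == ".trend"])
}

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power
#' parameterization: linear beyond the boundary knots, with k knots giving
#' k - 1 basis columns (the linear term plus k - 2 restricted cubic terms).
#' With the analysis default of 3 knots at the 10th, 50th and 90th
#' percentiles this is a 2-column basis.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot locations.
#' @return matrix with `length(knots) - 1` columns; attribute `"knots"`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  if (any(duplicated(knots))) stop("duplicate knots")
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots")
  pos3 <- function(u) pmax(u, 0)^3
  kk <- knots[k]
  km <- knots[k - 1]
  scale2 <- (kk - knots[1])^2
  out <- matrix(x, ncol = 1)
  for (j in seq_len(k - 2)) {
    term <- (pos3(x - knots[j]) -
               pos3(x - km) * (kk - knots[j]) / (kk - km) +
               pos3(x - kk) * (km - knots[j]) / (kk - km)) / scale2
    out <- cbind(out, term)
  }
  colnames(out) <- c("lin", paste0("cub", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Spline dose-response curve relative to a reference point
#'
#' Fits the outcome on a restricted-cubic-spline expansion of the exposure
#' (knots at the 10th, 50th and 90th percentiles by default) plus
#' covariates, and returns the fitted difference curve relative to a
#' reference exposure value (in the cohort analysis: the median of the
#' bottom sex-specific tertile), with pointwise 95% CIs. At the reference
#' itself the difference and its CI width are exactly zero.
#'
#' @param data analysis data frame.
#' @param outcome,exposure column names.
#' @param covariates adjustment columns.
#' @param ref reference exposure value.
#' @param knots knot locations; default quantiles (0.10, 0.50, 0.90) of the
#'   exposure.
#' @param eval_points exposure grid; defaults to 101 points over the range.
#' @return tibble: `x`, `diff`, `ci_low`, `ci_high`; attribute `"knots"`.
#' @export
spline_curve <- function(data, outcome, exposure, covariates = character(),
                         ref, knots = NULL, eval_points = NULL) {
  x <- data[[exposure]]
  if (is.null(knots)) {
    knots <- stats::quantile(x, c(0.10, 0.50, 0.90), names = FALSE)
  }
  if (any(duplicated(knots))) stop("duplicate knots")
  basis <- rcs_basis(x, knots)
  bd <- as.data.frame(basis)
  names(bd) <- paste0(".rcs_", names(bd))
  dd <- cbind(data, bd)
  fit_tbl <- fit_linear(dd, outcome, c(names(bd), covariates))
  fit <- attr(fit_tbl, "fit")
  beta <- stats::coef(fit)[names(bd)]
  V <- stats::vcov(fit)[names(bd), names(bd)]

  if (is.null(eval_points)) eval_points <- seq(min(x), max(x), length.out = 101)
  b_eval <- rcs_basis(eval_points, knots)
  b_ref <- rcs_basis(ref, knots)
  delta <- sweep(b_eval, 2, as.numeric(b_ref))
  est <- drop(delta %*% beta)
  se <- sqrt(pmax(0, rowSums((delta %*% V) * delta)))
  crit <- stats::qt(0.975, fit$df.residual)
  tibble::tibble(x = eval_points, diff = est,
                 ci_low = est - crit * se, ci_high = est + crit * se) |>
    structure(knots = knots)
}

# ---- multiple imputation by chained equations --------------------------------

impute_variable_type <- function(v) {
  if (is.logical(v)) return("binary")
  if (is.factor(v)) return(if (nlevels(v) == 2) "binary" else "multinomial")
  if (is.numeric(v)) return("continuous")
  stop("cannot impute variable of class ", paste(class(v), collapse = "/"))
}

# Design matrix of predictors (all columns except the target), using the
# currently filled-in data.
impute_design <- function(data, target) {
  preds <- setdiff(names(data), target)
  stats::model.matrix(~ ., data = data[preds])
}

draw_continuous <- function(y_obs, X_obs, X_mis) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_obs, y_obs)
  dfres <- length(y_obs) - ncol(X_obs)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / stats::rchisq(1, max(dfres, 1))
  xtx_inv <- chol2inv(chol(crossprod(X_obs)))
  beta <- MASS::mvrnorm(1, fit$coefficients, sigma2 * xtx_inv)
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

draw_binary <- function(y_obs, X_obs, X_mis) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X_obs, y_obs, family = stats::binomial())
  )
  V <- tryCatch(chol2inv(chol(crossprod(X_obs * sqrt(pmax(fit$weights, 1e-8))))),
                error = function(e) diag(1e-6, ncol(X_obs)))
  beta <- MASS::mvrnorm(1, fit$coefficients, V)
  p <- stats::plogis(drop(X_mis %*% beta))
  stats::runif(nrow(X_mis)) < p
}

draw_multinomial <- function(y_obs, pred_obs, pred_mis) {
  df_obs <- cbind(.y = y_obs, pred_obs)
  fit <- nnet::multinom(.y ~ ., data = df_obs, trace = FALSE)
  pp <- stats::predict(fit, newdata = pred_mis, type = "probs")
  if (is.null(dim(pp))) pp <- matrix(pp, nrow = nrow(pred_mis))
  levs <- fit$lev
  if (ncol(pp) == 1) pp <- cbind(1 - pp, pp)  # two observed classes
  apply(pp, 1, function(p) sample(levs, 1, prob = p))
}

#' Multiple imputation by chained equations
#'
#' Fills missing covariate values by iteratively cycling over the incomplete
#' variables, drawing each from a conditional model given all other
#' variables: Bayesian normal linear regression for continuous variables,
#' Bayesian logistic regression for binary variables, and multinomial
#' regression for categorical variables. Complete columns are never touched.
#' With the analysis defaults (`m` = 10 imputations, `maxit` = 10
#' iterations) and a fixed seed the result is deterministic.
#'
#' @param data data frame; missingness is only allowed in covariate columns.
#' @param m number of imputed datasets (default 10).
#' @param maxit chained-equation iterations per dataset (default 10).
#' @param seed RNG seed (set once, covering all imputations).
#' @param id_cols identifier columns excluded from the imputation models
#'   (default `"patient_id"`).
#' @param must_be_complete columns required to have no missing values
#'   (e.g. outcome and exposure); an error if violated.
#' @return list of `m` completed tibbles; attribute `"imputed_columns"`.
#' @export
mice_impute <- function(data, m = 10, maxit = 10, seed = NULL,
                        id_cols = intersect("patient_id", names(data)),
                        must_be_complete = character()) {
  data <- tibble::as_tibble(data)
  for (col in must_be_complete) {
    if (anyNA(data[[col]])) stop("column '", col, "' must be complete (outcome/exposure)")
  }
  if (!is.null(seed)) set.seed(seed)
  work_cols <- setdiff(names(data), id_cols)
  miss_frac <- vapply(data[work_cols], function(v) mean(is.na(v)), numeric(1))
  if (any(miss_frac == 1)) {
    stop("all-missing column(s): ", paste(work_cols[miss_frac == 1], collapse = ", "))
  }
  if (any(miss_frac > 0.5)) {
    warning("column(s) with > 50% missing: ",
            paste(work_cols[miss_frac > 0.5], collapse = ", "))
  }
  incomplete <- work_cols[miss_frac > 0]
  if (length(incomplete) == 0) return(replicate(m, data, simplify = FALSE))

  masks <- lapply(data[incomplete], is.na)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    filled <- data
    # initial fill: sample from the observed values of each column
    for (v in incomplete) {
      obs <- filled[[v]][!masks[[v]]]
      filled[[v]][masks[[v]]] <- sample(obs, sum(masks[[v]]), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in incomplete) {
        mis <- masks[[v]]
        type <- impute_variable_type(data[[v]])
        if (type == "multinomial") {
          preds <- setdiff(work_cols, v)
          drawn <- draw_multinomial(
            droplevels(data[[v]][!mis]),
            as.data.frame(filled[!mis, preds]),
            as.data.frame(filled[mis, preds])
          )
          filled[[v]][mis] <- factor(drawn, levels = levels(data[[v]]))
        } else {
          X <- impute_design(filled[work_cols], v)
          if (type == "continuous") {
            filled[[v]][mis] <- draw_continuous(data[[v]][!mis],
                                                X[!mis, , drop = FALSE],
                                                X[mis, , drop = FALSE])
          } else {
            drawn <- draw_binary(as.numeric(data[[v]][!mis]) -
                                   if (is.factor(data[[v]])) 1 else 0,
                                 X[!mis, , drop = FALSE],
                                 X[mis, , drop = FALSE])
            filled[[v]][mis] <- if (is.factor(data[[v]])) {
              factor(levels(data[[v]])[drawn + 1], levels = levels(data[[v]]))
            } else {
              drawn
            }
          }
        }
      }
    }
    out[[k]] <- filled
  }
  attr(out, "imputed_columns") <- incomplete
  out
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled point estimate \eqn{\bar q} is the mean of the per-imputation
#' estimates; total variance is \eqn{T = \bar W + (1 + 1/m) B} with
#' \eqn{\bar W} the mean within-imputation variance and \eqn{B} the
#' between-imputation variance. Degrees of freedom follow Rubin, with the
#' Barnard--Rubin small-sample adjustment when the complete-data degrees of
#' freedom are finite. With \eqn{B = 0} (or a single imputation) the result
#' reduces exactly to the single-fit estimate and CI.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors (same length).
#' @param df_com complete-data residual degrees of freedom (`Inf` for the
#'   asymptotic normal reference).
#' @return one-row tibble: `m`, `q_bar`, `w_bar`, `b`, `t_var`, `df`, `se`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have the same length")
  }
  m <- length(estimates)
  q_bar <- mean(estimates)
  w_bar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  t_var <- w_bar + (1 + 1 / m) * b
  if (m == 1 || b == 0) {
    df <- df_com
  } else {
    lambda <- (1 + 1 / m) * b / t_var
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else {
      df_old
    }
  }
  se <- sqrt(t_var)
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  p <- if (is.finite(df)) {
    2 * stats::pt(abs(q_bar / se), df, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(q_bar / se), lower.tail = FALSE)
  }
  tibble::tibble(m = m, q_bar = q_bar, w_bar = w_bar, b = b, t_var = t_var,
                 df = df, se = se, ci_low = q_bar - crit * se,
                 ci_high = q_bar + crit * se, p = p)
}

#' Covariate lists of the adjustment models
#'
#' Model 1 (basic): age, sex, education, total energy intake. Model 2 (main
#' model): model 1 plus smoking status, physical activity, RAAS-blocker use
#' and lipid-lowering medication. Model 3: model 2 plus potential
#' intermediates (SBP, BMI, diabetes, HDL cholesterol). `component_M2` adds
#' all other diet-component scores to model 2; `genetic_M2` adds the first
#' three genetic principal components. The nesting M1 within M2 within M3
#' holds by construction.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"component_M2"`,
#'   `"genetic_M2"`.
#' @param other_components score columns to add for `component_M2`.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(model = c("M1", "M2", "M3", "component_M2", "genetic_M2"),
                             other_components = character()) {
  model <- match.arg(model)
  m1 <- c("age", "sex", "education", "energy")
  m2 <- c(m1, "smoking", "physical_activity", "raas", "lipid_lowering")
  m3 <- c(m2, "sbp", "bmi", "diabetes", "hdl")
  switch(model,
         M1 = m1,
         M2 = m2,
         M3 = m3,
         component_M2 = c(m2, other_components),
         genetic_M2 = c(m2, "pc1", "pc2", "pc3"))
}

# Fit one exposure/model on complete data or a list of imputed datasets,
# pooling with Rubin's rules, and return the focus-term row.
fit_exposure_model <- function(data_list, outcome, exposure_col, covariates) {
  ests <- numeric(length(data_list))
  vars <- numeric(length(data_list))
  dfc <- NA_real_
  n <- NA_integer_
  for (i in seq_along(data_list)) {
    tab <- fit_linear(data_list[[i]], outcome, c(exposure_col, covariates))
    row <- tab[tab$term == exposure_col, ]
    ests[i] <- row$beta
    vars[i] <- row$se^2
    dfc <- row$df
    n <- row$n
  }
  pooled <- pool_rubin(ests, vars, df_com = dfc)
  tibble::tibble(n = n, beta = pooled$q_bar, se = pooled$se,
                 ci_low = pooled$ci_low, ci_high = pooled$ci_high, p = pooled$p)
}

#' Run the diet--kidney model suite
#'
#' Estimates the association of one or more exposures with annual eGFR
#' change under the adjustment models, overall and within subgroups, with
#' per-1-SD exposure scaling and Rubin pooling across imputed datasets.
#'
#' @param data analysis tibble, or a list of imputed analysis tibbles from
#'   [mice_impute()] (exposure and outcome must be identical across
#'   imputations).
#' @param exposures list of exposure descriptors; each a list with `name`
#'   (label), `column`, and `type` (`"per_sd_increment"`,
#'   `"per_sd_decrease"`, or `"binary"` for consumer contrasts).
#' @param models character vector of model ids (see [model_covariates()]).
#' @param outcome outcome column (default `"annual_change"`).
#' @param subgroups named list mapping a subgroup label to a column name;
#'   the suite is rerun within each level of that column.
#' @param min_subgroup minimum stratum size; smaller strata are skipped and
#'   logged (default 30).
#' @param other_components component-score columns for `component_M2`.
#' @return tidy tibble with one row per exposure x model x stratum:
#'   `exposure`, `unit`, `model`, `subgroup`, `n`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`; attribute `"skipped"` lists skipped strata.
#' @export
run_model_suite <- function(data,
                            exposures = list(list(name = "dhd_total",
                                                  column = "total",
                                                  type = "per_sd_increment")),
                            models = c("M1", "M2", "M3"),
                            outcome = "annual_change",
                            subgroups = NULL,
                            min_subgroup = 30,
                            other_components = character()) {
  data_list <- if (is.data.frame(data)) list(data) else data
  base <- data_list[[1]]
  rows <- list()
  skipped <- list()

  strata <- list(list(label = "all", idx = seq_len(nrow(base))))
  for (sg_label in names(subgroups)) {
    col <- subgroups[[sg_label]]
    vals <- base[[col]]
    for (lev in sort(unique(as.character(vals[!is.na(vals)])))) {
      strata[[length(strata) + 1]] <- list(
        label = paste0(sg_label, "=", lev),
        idx = which(!is.na(vals) & as.character(vals) == lev)
      )
    }
  }

  for (st in strata) {
    if (length(st$idx) < min_subgroup) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        subgroup = st$label, n = length(st$idx),
        reason = sprintf("below minimum subgroup size (%d)", min_subgroup))
      next
    }
    sub_list <- lapply(data_list, function(d) d[st$idx, , drop = FALSE])
    for (ex in exposures) {
      xcol <- ex$column
      if (ex$type %in% c("per_sd_increment", "per_sd_decrease")) {
        dir <- if (ex$type == "per_sd_increment") "increment" else "decrease"
        scaled <- standardize_exposure(sub_list[[1]][[xcol]], dir)
        unit <- sprintf("per 1-SD %s (SD = %.3g)", dir, attr(scaled, "sd"))
        sub_list <- lapply(sub_list, function(d) {
          d$.exposure <- as.numeric(scaled)
          d
        })
        use_col <- ".exposure"
      } else {
        sub_list <- lapply(sub_list, function(d) {
          d$.exposure <- as.numeric(as.logical(d[[xcol]]))
          d
        })
        unit <- "consumers vs non-consumers"
        use_col <- ".exposure"
      }
      for (mod in models) {
        covs <- model_covariates(mod, other_components = setdiff(other_components,
                                                                 paste0("score_", ex$name)))
        # drop covariates constant within the stratum (e.g. the variable the
        # stratum is defined by), which would otherwise be collinear
        keep_cov <- vapply(covs, function(cv) {
          v <- sub_list[[1]][[cv]]
          length(unique(v[!is.na(v)])) > 1
        }, logical(1))
        est <- fit_exposure_model(sub_list, outcome, use_col, covs[keep_cov])
        rows[[length(rows) + 1]] <- tibble::tibble(
          exposure = ex$name, unit = unit, model = mod, subgroup = st$label,
          n = est$n, beta = est$beta, se = est$se,
          ci_low = est$ci_low, ci_high = est$ci_high, p = est$p)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(subgroup = character(), n = integer(), reason = character())
  out
}
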
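test_that("obesity and diabetes flags follow the clinical definitions", {
  cov <- tibble::tibble(
    bmi = c(30.0, 29.9, 25, 25),
    glucose = c(5, 7.2, 7.2, 11.2),
    fasted_gt_4h = c(TRUE, TRUE, FALSE, FALSE),
    diabetes_self_report = FALSE,
    glucose_lowering_med = FALSE)
  out <- derive_flags(cov)
  expect_equal(out$obesity, c(TRUE, FALSE, FALSE, FALSE))
  # fasted 7.2 -> diabetic; non-fasted 7.2 -> not; non-fasted 11.2 -> diabetic
  expect_equal(out$diabetes, c(FALSE, TRUE, FALSE, TRUE))
  # medication alone suffices even with missing glucose
  out2 <- derive_flags(tibble::tibble(bmi = 25, glucose = NA_real_,
                                      fasted_gt_4h = TRUE,
                                      diabetes_self_report = FALSE,
                                      glucose_lowering_med = TRUE))
  expect_true(out2$diabetes)
  expect_error(derive_flags(tibble::tibble(bmi = 25, glucose = 5,
                                           fasted_gt_4h = TRUE,
                                           diabetes_self_report = FALSE,
                                           glucose_lowering_med = FALSE,
                                           education = "phd")),
               "out-of-domain")
})

test_that("per-1-SD scaling is unit-norm and direction-aware", {
  set.seed(1)
  x <- rnorm(500, 80, 15)
  up <- standardize_exposure(x, "increment")
  expect_equal(sd(up), 1)
  expect_equal(attr(up, "sd"), sd(x))
  # +1 SD in raw units is +1 scaled unit
  expect_equal(up[which.max(x)] - (max(x) - sd(x) - mean(x)) / sd(x), 1)
  down <- standardize_exposure(x, "decrease")
  expect_equal(as.numeric(down), -as.numeric(up))  # flipping direction negates
  expect_error(standardize_exposure(rep(3, 10)), "zero variance")
})

test_that("fit_linear recovers exact and simulated coefficients", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  out <- suppressWarnings(fit_linear(d, "y", "x"))  # exact fit: zero residual
  expect_equal(out$beta[out$term == "x"], 2.0, tolerance = 1e-12)
  expect_lt(out$se[out$term == "x"], 1e-10)

  # normal-equations oracle on a random well-conditioned design
  set.seed(2)
  X <- cbind(1, matrix(rnorm(300 * 3), 300))
  beta <- c(0.5, -1, 2, 0.3)
  y <- drop(X %*% beta) + rnorm(300)
  d2 <- tibble::tibble(y = y, a = X[, 2], b = X[, 3], c = X[, 4])
  out2 <- fit_linear(d2, "y", c("a", "b", "c"))
  oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(out2$beta, drop(oracle)[c(1, 2, 3, 4)][match(out2$term,
               c("(Intercept)", "a", "b", "c"))], tolerance = 1e-10)

  # large-n simulated slope lands within the sampling-error bound
  set.seed(3)
  n <- 100000
  z <- rnorm(n)
  yy <- -0.2 * z + rnorm(n, 0, 3.86)
  out3 <- fit_linear(tibble::tibble(y = yy, z = z), "y", "z")
  expect_lt(abs(out3$beta[out3$term == "z"] + 0.2), 3 * 3.86 / sqrt(n))

  # rank deficiency names the collinear column
  d3 <- tibble::tibble(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(fit_linear(d3, "y", c("a", "b")), "collinear.*b")
})

test_that("permuted outcomes give nominal CI coverage of zero", {
  set.seed(4)
  n <- 80
  x <- rnorm(n)
  covers <- vapply(1:500, function(i) {
    y <- sample(rnorm(n))  # no association by construction
    out <- fit_linear(tibble::tibble(y = y, x = x), "y", "x")
    out$ci_low[2] <= 0 && 0 <= out$ci_high[2]
  }, logical(1))
  expect_gt(mean(covers), 0.92)
  expect_lt(mean(covers), 0.98)
})

test_that("tertile contrasts use T1 as reference and detect planted trends", {
  set.seed(5)
  n <- 900
  tert <- factor(rep(c("T1", "T2", "T3"), each = n / 3))
  y0 <- rnorm(n, 0, 1)
  null_fit <- tertile_model(tibble::tibble(y = y0, g = tert), "y", "g")
  expect_setequal(null_fit$estimates$term, c("T2", "T3"))
  expect_gt(null_fit$p_trend, 0.05)

  y1 <- y0 + 0.5 * (as.integer(tert) - 1)
  trend_fit <- tertile_model(tibble::tibble(y = y1, g = tert), "y", "g")
  expect_lt(trend_fit$p_trend, 0.05)
  b <- trend_fit$estimates$beta
  expect_true(b[2] > b[1])
  expect_error(tertile_model(tibble::tibble(y = y0[1:10],
                                            g = factor(rep("T1", 10),
                                                       levels = c("T1", "T2"))),
                             "y", "g"), "empty")
})

test_that("the restricted cubic spline basis is linear in the tails", {
  knots <- c(2, 5, 8)
  x_low <- seq(0, 2, 0.1)
  b <- rcs_basis(x_low, knots)
  expect_equal(ncol(b), 2)  # 3 knots -> 2 basis columns
  expect_equal(b[, "cub1"], rep(0, length(x_low)))  # pure linear below knot 1
  # above the last knot the basis is affine in x: second differences vanish
  x_hi <- seq(9, 20, 0.5)
  bh <- rcs_basis(x_hi, knots)[, "cub1"]
  expect_equal(diff(diff(bh)), rep(0, length(x_hi) - 2), tolerance = 1e-9)
  expect_error(rcs_basis(1:10, c(2, 2, 8)), "duplicate")
})

test_that("rcs basis spans the same fit as the natural-spline reference", {
  set.seed(6)
  x <- runif(400, 0, 10)
  y <- sin(x / 3) + rnorm(400, 0, 0.2)
  knots <- quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  own <- lm(y ~ rcs_basis(x, knots))
  ref <- lm(y ~ splines::ns(x, knots = knots[2],
                            Boundary.knots = knots[c(1, 3)]))
  expect_equal(fitted(own), fitted(ref), tolerance = 1e-8)
})

test_that("spline curve is zero at the reference and linear truths stay linear", {
  set.seed(7)
  n <- 1500
  x <- runif(n, 50, 110)
  d <- tibble::tibble(x = x, y = -0.05 * x + rnorm(n, 0, 1))
  ref <- 70
  cur <- spline_curve(d, "y", "x", ref = ref, eval_points = c(55, 70, 100))
  at_ref <- cur[cur$x == ref, ]
  expect_equal(at_ref$diff, 0)
  expect_equal(at_ref$ci_high - at_ref$ci_low, 0)
  # under a linear truth the curve tracks the line to within ~4 pointwise SEs
  truth <- -0.05 * (cur$x - ref)
  se <- (cur$ci_high - cur$ci_low) / (2 * qt(0.975, n - 3))
  expect_true(all(abs(cur$diff - truth) <= 4 * se + 1e-9))
  # and the restricted cubic coefficient itself is compatible with zero
  knots <- quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  b <- as.data.frame(rcs_basis(x, knots))
  fit <- fit_linear(cbind(d, b), "y", c("lin", "cub1"))
  expect_gt(fit$p[fit$term == "cub1"], 0.001)
})

test_that("Rubin pooling matches the closed-form hand example", {
  p <- pool_rubin(c(0.9, 1.1), c(0.04, 0.04))
  expect_equal(p$q_bar, 1.0)
  expect_equal(p$b, 0.02)
  expect_equal(p$t_var, 0.04 + 1.5 * 0.02)
  expect_equal(p$t_var, 0.07)
})

test_that("Rubin pooling degenerates correctly", {
  # B = 0 reduces exactly to the single-fit variance and CI
  single <- pool_rubin(1.0, 0.04, df_com = 50)
  dup <- pool_rubin(c(1.0, 1.0), c(0.04, 0.04), df_com = 50)
  expect_equal(dup$t_var, 0.04)
  expect_equal(dup$ci_low, single$ci_low)
  expect_equal(dup$ci_high, single$ci_high)
  expect_equal(single$ci_low, 1 - qt(0.975, 50) * 0.2)
  # pooled variance is monotone non-decreasing in B
  ts <- vapply(c(0, 0.05, 0.1, 0.2), function(delta) {
    pool_rubin(c(1 - delta, 1 + delta), c(0.04, 0.04))$t_var
  }, numeric(1))
  expect_true(all(diff(ts) >= 0))
  expect_error(pool_rubin(1:3, 1:2), "same length")
})

test_that("chained-equation imputation is a no-op on complete data", {
  d <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  out <- mice_impute(d, m = 3, seed = 1)
  expect_length(out, 3)
  expect_equal(out[[1]], d)
  expect_equal(out[[3]], d)
})

test_that("imputation preserves domains and is deterministic under a seed", {
  set.seed(8)
  n <- 200
  d <- tibble::tibble(
    x = rnorm(n),
    flag = runif(n) < 0.4,
    cat = factor(sample(c("a", "b", "c"), n, TRUE)),
    y = rnorm(n))
  d$flag[sample(n, 20)] <- NA
  d$cat[sample(n, 20)] <- NA
  d$x[sample(n, 20)] <- NA
  out1 <- mice_impute(d, m = 2, maxit = 3, seed = 99)
  out2 <- mice_impute(d, m = 2, maxit = 3, seed = 99)
  expect_identical(out1, out2)
  for (k in 1:2) {
    expect_false(anyNA(out1[[k]]))
    expect_type(out1[[k]]$flag, "logical")
    expect_true(all(levels(out1[[k]]$cat) == c("a", "b", "c")))
  }
  # observed entries are untouched
  obs <- !is.na(d$x)
  expect_equal(out1[[1]]$x[obs], d$x[obs])
  expect_error(mice_impute(dplyr::mutate(d, all_na = NA_real_), m = 1),
               "all-missing")
  expect_error(mice_impute(d, m = 1, must_be_complete = "x"), "complete")
})

test_that("imputation recovers a planted regression under MCAR", {
  set.seed(12)
  reps <- 30
  bias <- vapply(seq_len(reps), function(i) {
    n <- 400
    x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
    y <- 1 + 0.5 * x1 + 0.3 * x2 + rnorm(n)
    d <- tibble::tibble(y = y, x1 = x1, x2 = x2)
    d$x1[sample(n, 40)] <- NA  # 10% MCAR
    imp <- mice_impute(d, m = 5, maxit = 5)
    ests <- vapply(imp, function(dd) {
      f <- fit_linear(dd, "y", c("x1", "x2")); f$beta[f$term == "x1"]
    }, numeric(1))
    vars <- vapply(imp, function(dd) {
      f <- fit_linear(dd, "y", c("x1", "x2")); f$se[f$term == "x1"]^2
    }, numeric(1))
    pool_rubin(ests, vars)$q_bar - 0.5
  }, numeric(1))
  # mean bias across replicates is within 3 Monte-Carlo SEs of zero
  expect_lt(abs(mean(bias)), 3 * sd(bias) / sqrt(reps))
})

test_that("model covariate lists are strictly nested", {
  m1 <- model_covariates("M1")
  m2 <- model_covariates("M2")
  m3 <- model_covariates("M3")
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))
  expect_gt(length(m2), length(m1))
  expect_gt(length(m3), length(m2))
  expect_true(all(c("pc1", "pc2", "pc3") %in% model_covariates("genetic_M2")))
  expect_true("score_fruit" %in%
                model_covariates("component_M2", other_components = "score_fruit"))
})

test_that("the model suite is deterministic and handles small subgroups", {
  coh <- generate_cohort(synthetic_config(n_patients = 300,
                                          include_genetics = FALSE,
                                          missing_rates = numeric(0)), seed = 6)
  kid <- annual_change(coh$serum)$kidney
  dat <- score_index(coh$intake) |>
    dplyr::inner_join(kid[c("patient_id", "annual_change")], by = "patient_id") |>
    dplyr::inner_join(dplyr::select(coh$covariates, -"sex"), by = "patient_id")
  dat$tiny <- c(rep(TRUE, 5), rep(FALSE, nrow(dat) - 5))
  r1 <- run_model_suite(dat, models = c("M1", "M2"),
                        subgroups = list(size = "tiny"))
  r2 <- run_model_suite(dat, models = c("M1", "M2"),
                        subgroups = list(size = "tiny"))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  skipped <- attr(r1, "skipped")
  expect_equal(skipped$subgroup, "size=TRUE")
  expect_true(all(c("size=FALSE") %in% r1$subgroup))
  expect_true(all(r1$ci_low <= r1$beta & r1$beta <= r1$ci_high))
})
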
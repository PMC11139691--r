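test_that("component worked examples reproduce the published median scores", {
  rules <- dhd_cvd_ruleset()
  expect_equal(score_component(data.frame(fruit = 110), rules$fruit), 5.50)
  expect_equal(round(score_component(data.frame(tea = 150), rules$tea), 2), 3.33)
  expect_equal(score_component(data.frame(ssb_juice = 160.5), rules$ssb_juice), 3.58)
  expect_equal(score_component(data.frame(red_meat = 37.1), rules$red_meat), 10.0)
})

test_that("every component attains its maximum at the full-adherence threshold", {
  rules <- dhd_cvd_ruleset()
  expect_equal(score_component(data.frame(fruit = 200), rules$fruit), 10)
  expect_equal(score_component(data.frame(red_meat = 45), rules$red_meat), 10)
  expect_equal(score_component(data.frame(dairy = 300), rules$dairy), 10)
  expect_equal(score_component(data.frame(dairy = 450), rules$dairy), 10)
  expect_equal(score_component(data.frame(whole_grains = 50, refined_grains = 50),
                               rules$grains), 10)
  expect_equal(score_component(data.frame(sodium = 1900), rules$sodium), 10)
  expect_equal(score_component(data.frame(sterol_use = TRUE), rules$sterols), 10)
})

test_that("alcohol thresholds are sex-specific", {
  rules <- dhd_cvd_ruleset()
  # 20 g/d: zero for women (cutoff 20), halfway for men (cutoff 30)
  d <- data.frame(alcohol = c(20, 20), sex = c("female", "male"))
  expect_equal(score_component(d, rules$alcohol), c(0, 5))
})

test_that("missing or negative intakes are rejected with the component named", {
  rules <- dhd_cvd_ruleset()
  expect_error(score_component(data.frame(tea = 100), rules$fruit), "fruit")
  expect_error(score_component(data.frame(fruit = -1), rules$fruit), "negative")
  expect_error(score_component(data.frame(fruit = NA_real_), rules$fruit), "missing")
})

test_that("a fully adherent profile scores the theoretical maximum of 150", {
  expect_equal(score_index(perfect_intake())$total, 150)
})

test_that("zero intake scores only the moderation and zero-denominator components", {
  z <- zero_intake()
  expect_equal(score_index(z)$total, oracle_total_score(z))
  expect_equal(score_index(z)$total, 70)
})

test_that("score_index equals the brute-force per-component oracle on random patients", {
  intakes <- random_intakes(100)
  got <- score_index(intakes)$total
  want <- vapply(seq_len(nrow(intakes)), function(i) {
    oracle_total_score(as.list(intakes[i, ]))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("totals are additive in single-component changes within a ramp", {
  x <- random_intakes(1)
  base <- score_index(x)$total
  x2 <- x
  x2$fruit <- x$fruit + 7
  rules <- dhd_cvd_ruleset()
  delta <- score_component(x2, rules$fruit) - score_component(x, rules$fruit)
  expect_equal(score_index(x2)$total, base + delta)
})

test_that("scores are bounded and monotone across a random sweep", {
  rules <- dhd_cvd_ruleset()
  set.seed(7)
  for (comp in c("vegetables", "fruit", "legumes", "fish", "tea")) {
    x <- sort(runif(1000, 0, 800))
    d <- data.frame(x)
    names(d) <- comp
    s <- score_component(d, rules[[comp]])
    expect_true(all(s >= 0 & s <= 10))
    expect_true(all(diff(s) >= 0))  # adequacy: non-decreasing
  }
  for (comp in c("red_meat", "processed_meat", "ssb_juice", "sodium")) {
    x <- sort(runif(1000, 0, 5000))
    d <- data.frame(x)
    names(d) <- comp
    s <- score_component(d, rules[[comp]])
    expect_true(all(s >= 0 & s <= 10))
    expect_true(all(diff(s) <= 0))  # moderation: non-increasing
  }
})

test_that("median score equals score of median intake for monotone components", {
  rules <- dhd_cvd_ruleset()
  set.seed(11)
  x <- rlnorm(999, log(110), 1.3)  # odd n: the median is an observed value
  d <- data.frame(fruit = x)
  expect_equal(median(score_component(d, rules$fruit)),
               score_component(data.frame(fruit = median(x)), rules$fruit))
})

test_that("score_index validates patient ids and ruleset composition", {
  two <- dplyr::bind_rows(perfect_intake("A"), perfect_intake("A"))
  expect_error(score_index(two), "duplicate")
  rules <- dhd_cvd_ruleset()
  expect_error(score_index(perfect_intake(), rules[-1]), "missing")
  bad <- rules
  bad$coffee <- component_rule("vegetables", "adequacy", x_zero = 0, x_full = 1)
  bad$coffee$name <- "coffee"
  expect_error(score_index(perfect_intake(), bad), "unknown")
})

test_that("energy plausibility bounds are sex-specific and strict", {
  mk <- function(id, sex, energy) {
    x <- perfect_intake(id, sex); x$energy <- energy; x
  }
  intakes <- dplyr::bind_rows(
    mk("m_low", "male", 700), mk("f_edge", "female", 600),
    mk("m_ok", "male", 2000), mk("f_high", "female", 6500),
    mk("m_edge", "male", 8000))
  out <- apply_plausibility_filter(intakes)
  expect_setequal(out$kept$patient_id, c("f_edge", "m_ok", "m_edge"))
  expect_setequal(out$excluded$patient_id, c("m_low", "f_high"))
  expect_match(out$excluded$reason[out$excluded$patient_id == "m_low"], "low")
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(intakes))
  bad <- mk("x", "unknown", 2000)
  expect_error(apply_plausibility_filter(bad), "unknown sex")
})

test_that("sex-specific tertiles partition each sex into near-equal thirds", {
  scores <- tibble::tibble(
    patient_id = as.character(1:12),
    sex = rep(c("male", "female"), each = 6),
    total = c(1, 2, 3, 4, 5, 6, 10, 20, 30, 40, 50, 60))
  out <- assign_sex_specific_tertiles(scores)
  for (s in c("male", "female")) {
    expect_equal(as.integer(table(out$tertile[out$sex == s])), c(2L, 2L, 2L))
  }
  # brute-force quantile oracle for the male cutpoints
  q <- quantile(1:6, c(1/3, 2/3), names = FALSE)
  expect_equal(attr(out, "cutpoints")$male, q)
})

test_that("tertile ties at a cutpoint go to the upper stratum", {
  scores <- tibble::tibble(patient_id = as.character(1:9), sex = "female",
                           total = c(60, 65, 70, 77.1, 80, 85, 89.2, 95, 99))
  out <- assign_sex_specific_tertiles(scores)
  cuts <- attr(out, "cutpoints")$female
  at_cut <- which(abs(scores$total - cuts[2]) < 1e-9)
  if (length(at_cut)) expect_equal(as.character(out$tertile[at_cut]), "T3")
  # under the printed female cutpoints, a score equal to the upper cut is T3
  lab <- ifelse(89.2 < 77.1, "T1", ifelse(89.2 < 89.2, "T2", "T3"))
  expect_equal(lab, "T3")
  expect_error(assign_sex_specific_tertiles(
    tibble::tibble(patient_id = as.character(1:4), sex = "male", total = 5)),
    "degenerate")
})

test_that("consumer flags are strict zero/positive splits", {
  x <- dplyr::bind_rows(perfect_intake("a"), zero_intake("b"))
  x$legumes <- c(6.2, 0)
  flags <- derive_consumer_flags(x)
  expect_equal(flags$consumer_legumes, c(TRUE, FALSE))
  expect_equal(flags$consumer_fish, c(TRUE, FALSE))
  expect_equal(flags$consumer_sterols, c(TRUE, FALSE))
})

test_that("the shipped YAML ruleset matches the built-in default", {
  path <- system.file("extdata", "dhd_cvd_ruleset.yaml", package = "dhdkidney")
  expect_true(nzchar(path))
  loaded <- read_ruleset(path)
  expect_equal(lapply(loaded, unclass), lapply(dhd_cvd_ruleset(), unclass))
  # round-trip through a temp file
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(loaded, tmp)
  expect_equal(lapply(read_ruleset(tmp), unclass), lapply(loaded, unclass))
})

test_that("rule constructor enforces threshold ordering", {
  expect_error(component_rule("fruit", "adequacy", x_zero = 200, x_full = 0), "x_zero")
  expect_error(component_rule("red_meat", "moderation", x_full = 100, x_zero = 45),
               "x_full")
  expect_error(component_rule("grains", "ratio", numerator = "whole_grains"),
               "denominator")
})
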
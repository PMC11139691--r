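# The 15 analysis components of the DHD-CVD index (coffee omitted).
DHD_COMPONENTS <- c(
  "vegetables", "fruit", "grains", "legumes", "nuts", "dairy", "fish",
  "tea", "fats_oils", "red_meat", "processed_meat", "ssb_juice",
  "alcohol", "sodium", "sterols"
)

#' Construct a dietary component scoring rule
#'
#' A `component_rule` declares how one DHD-CVD component converts an intake
#' (grams/day, mg/day for sodium, or a use flag for plant sterols) into an
#' adherence score on 0--10 points. Five shapes are supported:
#'
#' * `adequacy`: 0 points at `x_zero`, rising linearly to 10 at `x_full`
#'   (e.g. fruit, 0 at 0 g/d to 10 at 200 g/d), capped above.
#' * `moderation`: full 10 points at or below `x_full`, falling linearly to 0
#'   at `x_zero` (e.g. red meat, 10 up to 45 g/d, 0 at 100 g/d).
#' * `optimum_range`: trapezoid -- rises `x_zero`..`x_full`, flat 10 on
#'   `x_full`..`x_full_upper`, falls to 0 at `x_zero_upper` (dairy).
#' * `ratio`: two-input rule on `numerator`/`denominator` intakes; 10 points
#'   when the denominator is zero or the ratio is at least 1, otherwise
#'   `10 * ratio` (grains, fats and oils).
#' * `binary`: 10 points for any use, 0 for zero use (plant sterol/stanol
#'   enriched products).
#'
#' @param name component identifier (one of the 15 index components).
#' @param shape one of `"adequacy"`, `"moderation"`, `"optimum_range"`,
#'   `"ratio"`, `"binary"`.
#' @param field intake column the rule reads (defaults to `name`).
#' @param x_zero intake at which the score is 0.
#' @param x_full intake at/beyond (adequacy) or at/below (moderation) which
#'   the score is maximal.
#' @param x_full_upper,x_zero_upper upper ramp bounds for `optimum_range`.
#' @param numerator,denominator intake columns for `ratio` shapes.
#' @param sex_specific optional named list (`male`, `female`) of field
#'   overrides, e.g. a sex-specific `x_zero` for alcohol.
#' @param max_points maximum score, fixed at 10 for the DHD-CVD index.
#' @return an object of class `component_rule`.
#' @export
component_rule <- function(name, shape,
                           field = name,
                           x_zero = NULL, x_full = NULL,
                           x_full_upper = NULL, x_zero_upper = NULL,
                           numerator = NULL, denominator = NULL,
                           sex_specific = NULL,
                           max_points = 10) {
  shape <- match.arg(shape, c("adequacy", "moderation", "optimum_range",
                              "ratio", "binary"))
  if (!identical(max_points, 10) && !identical(max_points, 10L)) {
    stop("max_points is fixed at 10 for DHD-CVD component rules")
  }
  if (shape == "adequacy" && !(x_zero < x_full)) {
    stop("adequacy rule requires x_zero < x_full: ", name)
  }
  if (shape == "moderation" && !(x_full < x_zero)) {
    stop("moderation rule requires x_full < x_zero: ", name)
  }
  if (shape == "optimum_range" &&
      !(x_zero < x_full && x_full <= x_full_upper && x_full_upper < x_zero_upper)) {
    stop("optimum_range rule requires x_zero < x_full <= x_full_upper < x_zero_upper: ", name)
  }
  if (shape == "ratio" && (is.null(numerator) || is.null(denominator))) {
    stop("ratio rule requires numerator and denominator fields: ", name)
  }
  structure(
    list(name = name, shape = shape, field = field,
         x_zero = x_zero, x_full = x_full,
         x_full_upper = x_full_upper, x_zero_upper = x_zero_upper,
         numerator = numerator, denominator = denominator,
         sex_specific = sex_specific, max_points = 10),
    class = "component_rule"
  )
}

#' @export
print.component_rule <- function(x, ...) {
  cat("<component_rule>", x$name, "--", x$shape, "\n")
  invisible(x)
}

#' The default DHD-CVD scoring ruleset
#'
#' Returns the 15 component rules of the DHD-CVD index as used in the
#' analysis (the coffee component is omitted). Thresholds follow the
#' published index conventions: vegetables and fruit adequacy 0 to 200 g/d;
#' legumes 0 to 10 g/d; unsalted nuts 0 to 15 g/d; fish 0 to 21 g/d; tea 0 to
#' 450 g/d; dairy trapezoid 0/300 and 450/750 g/d; red meat full points at or
#' below 45 g/d falling to 0 at 100 g/d; processed meat 10 at 0 g/d falling
#' to 0 at 50 g/d; sugar-sweetened beverages and juices 10 at 0 g/d falling
#' to 0 at 250 g/d; alcohol 10 at or below 10 g/d falling to 0 at 20 (women)
#' or 30 (men) g/d; sodium 10 at or below 1900 mg/d falling to 0 at
#' 3800 mg/d; whole:refined grains and liquid:solid fats as ratio rules;
#' plant sterol/stanol products binary. Every threshold can be overridden via
#' a YAML ruleset (see [read_ruleset()]).
#'
#' @return named list of [component_rule()] objects, class `dhd_ruleset`.
#' @export
dhd_cvd_ruleset <- function() {
  rules <- list(
    component_rule("vegetables", "adequacy", x_zero = 0, x_full = 200),
    component_rule("fruit", "adequacy", x_zero = 0, x_full = 200),
    component_rule("grains", "ratio",
                   numerator = "whole_grains", denominator = "refined_grains"),
    component_rule("legumes", "adequacy", x_zero = 0, x_full = 10),
    component_rule("nuts", "adequacy", field = "nuts_unsalted",
                   x_zero = 0, x_full = 15),
    component_rule("dairy", "optimum_range", x_zero = 0, x_full = 300,
                   x_full_upper = 450, x_zero_upper = 750),
    component_rule("fish", "adequacy", x_zero = 0, x_full = 21),
    component_rule("tea", "adequacy", x_zero = 0, x_full = 450),
    component_rule("fats_oils", "ratio",
                   numerator = "liquid_fats", denominator = "solid_fats"),
    component_rule("red_meat", "moderation", x_full = 45, x_zero = 100),
    component_rule("processed_meat", "moderation", x_full = 0, x_zero = 50),
    component_rule("ssb_juice", "moderation", x_full = 0, x_zero = 250),
    component_rule("alcohol", "moderation", x_full = 10, x_zero = 30,
                   sex_specific = list(female = list(x_zero = 20))),
    component_rule("sodium", "moderation", field = "sodium",
                   x_full = 1900, x_zero = 3800),
    component_rule("sterols", "binary", field = "sterol_use")
  )
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "dhd_ruleset")
}

# Apply sex-specific field overrides to a rule (alcohol upper cutoff).
resolve_rule <- function(rule, sex) {
  ov <- rule$sex_specific[[as.character(sex)]]
  if (!is.null(ov)) rule[names(ov)] <- ov
  rule
}

#' Score one dietary component
#'
#' Evaluates a [component_rule()] on per-patient intake records. Scores are
#' piecewise linear, clamped to 0--10, deterministic, and monotone on each
#' linear piece (non-decreasing in intake for adequacy shapes,
#' non-increasing for moderation).
#'
#' @param intake a data frame of intake records with the columns the rule
#'   reads (and `sex` if the rule has sex-specific thresholds).
#' @param rule a [component_rule()].
#' @return numeric vector of scores in `[0, 10]`, one per row of `intake`.
#' @examples
#' rules <- dhd_cvd_ruleset()
#' score_component(data.frame(fruit = 110), rules$fruit)   # 5.5
#' score_component(data.frame(tea = 150), rules$tea)       # 3.33
#' @export
score_component <- function(intake, rule) {
  stopifnot(inherits(rule, "component_rule"))
  intake <- as.data.frame(intake)
  needs <- switch(rule$shape,
                  ratio = c(rule$numerator, rule$denominator),
                  rule$field)
  missing_cols <- setdiff(needs, names(intake))
  if (length(missing_cols) > 0) {
    stop("intake record lacks field(s) ", paste(missing_cols, collapse = ", "),
         " required by component '", rule$name, "'")
  }
  for (col in needs) {
    v <- intake[[col]]
    if (is.numeric(v)) {
      if (anyNA(v)) stop("missing value in intake field '", col,
                         "' for component '", rule$name, "'")
      if (any(v < 0)) stop("negative intake in field '", col,
                           "' for component '", rule$name, "'")
    }
  }

  if (!is.null(rule$sex_specific)) {
    if (!"sex" %in% names(intake)) {
      stop("component '", rule$name, "' has sex-specific thresholds but intake has no sex column")
    }
    sexes <- as.character(intake$sex)
    out <- numeric(nrow(intake))
    for (s in unique(sexes)) {
      idx <- sexes == s
      out[idx] <- score_shape(intake[idx, , drop = FALSE], resolve_rule(rule, s))
    }
    return(out)
  }
  score_shape(intake, rule)
}

score_shape <- function(intake, rule) {
  clamp01 <- function(z) pmin(1, pmax(0, z))
  switch(rule$shape,
    adequacy = {
      x <- intake[[rule$field]]
      10 * clamp01((x - rule$x_zero) / (rule$x_full - rule$x_zero))
    },
    moderation = {
      x <- intake[[rule$field]]
      ifelse(x <= rule$x_full, 10,
             10 * clamp01((rule$x_zero - x) / (rule$x_zero - rule$x_full)))
    },
    optimum_range = {
      x <- intake[[rule$field]]
      up <- clamp01((x - rule$x_zero) / (rule$x_full - rule$x_zero))
      down <- clamp01((rule$x_zero_upper - x) / (rule$x_zero_upper - rule$x_full_upper))
      10 * pmin(up, down)
    },
    ratio = {
      num <- intake[[rule$numerator]]
      den <- intake[[rule$denominator]]
      ifelse(den <= 0, 10, 10 * pmin(1, num / den))
    },
    binary = {
      x <- intake[[rule$field]]
      if (is.logical(x)) 10 * as.numeric(x) else 10 * as.numeric(x > 0)
    }
  )
}

#' Score the full DHD-CVD index for a cohort
#'
#' Applies a 15-component ruleset to each patient and sums the component
#' scores into the total index (theoretical range 0--150 points; higher is
#' better adherence to the Dutch dietary guidelines for CVD patients).
#'
#' @param intakes data frame of per-patient intake records; must contain
#'   `patient_id` (unique) and the intake columns the rules read.
#' @param ruleset a named list of [component_rule()]s; defaults to
#'   [dhd_cvd_ruleset()]. Must contain exactly the 15 analysis components.
#' @return a tibble (`patient_id`, `sex` if present, one `score_*` column per
#'   component, `total`).
#' @export
score_index <- function(intakes, ruleset = dhd_cvd_ruleset()) {
  intakes <- as.data.frame(intakes)
  if (!"patient_id" %in% names(intakes)) stop("intakes must have a patient_id column")
  if (anyDuplicated(intakes$patient_id)) {
    stop("duplicate patient_id in intake table: ",
         paste(unique(intakes$patient_id[duplicated(intakes$patient_id)]), collapse = ", "))
  }
  rule_names <- vapply(ruleset, `[[`, character(1), "name")
  unknown <- setdiff(rule_names, DHD_COMPONENTS)
  if (length(unknown) > 0) {
    stop("unknown component(s) in ruleset: ", paste(unknown, collapse = ", "))
  }
  if (!setequal(rule_names, DHD_COMPONENTS)) {
    stop("ruleset must contain exactly the 15 DHD-CVD analysis components; missing: ",
         paste(setdiff(DHD_COMPONENTS, rule_names), collapse = ", "))
  }
  scores <- lapply(ruleset, function(r) score_component(intakes, r))
  names(scores) <- paste0("score_", rule_names)
  out <- tibble::tibble(patient_id = intakes$patient_id)
  if ("sex" %in% names(intakes)) out$sex <- intakes$sex
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  out$total <- rowSums(as.matrix(out[paste0("score_", rule_names)]))
  out
}

#' Energy-intake plausibility filter
#'
#' Partitions intake records into kept and excluded sets using sex-specific
#' plausible energy ranges. Defaults follow the cohort eligibility rule:
#' men are excluded below 800 or above 8000 kcal/day, women below 600 or
#' above 6000 kcal/day; bounds are strict, so a woman at exactly
#' 600 kcal/day is kept.
#'
#' @param intakes data frame with `patient_id`, `sex` and `energy` (kcal/day).
#' @param rules data frame (`sex`, `energy_min`, `energy_max`); defaults to
#'   the cohort rule above.
#' @return list with `kept` (tibble) and `excluded` (tibble of `patient_id`,
#'   `reason`).
#' @export
apply_plausibility_filter <- function(intakes,
                                      rules = plausibility_rules()) {
  intakes <- as.data.frame(intakes)
  stopifnot(all(c("patient_id", "sex", "energy") %in% names(intakes)))
  if (any(rules$energy_min >= rules$energy_max)) {
    stop("plausibility rule with energy_min >= energy_max")
  }
  sexes <- as.character(intakes$sex)
  bad_sex <- setdiff(unique(sexes), as.character(rules$sex))
  if (length(bad_sex) > 0) stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  idx <- match(sexes, as.character(rules$sex))
  lo <- rules$energy_min[idx]
  hi <- rules$energy_max[idx]
  too_low <- intakes$energy < lo
  too_high <- intakes$energy > hi
  drop <- too_low | too_high
  excluded <- tibble::tibble(
    patient_id = intakes$patient_id[drop],
    reason = ifelse(too_low[drop],
                    sprintf("implausible_energy_low (< %g kcal/day)", lo[drop]),
                    sprintf("implausible_energy_high (> %g kcal/day)", hi[drop]))
  )
  list(kept = tibble::as_tibble(intakes[!drop, , drop = FALSE]),
       excluded = excluded)
}

#' @rdname apply_plausibility_filter
#' @export
plausibility_rules <- function() {
  tibble::tibble(sex = c("male", "female"),
                 energy_min = c(800, 600),
                 energy_max = c(8000, 6000))
}

#' Sex-specific tertiles of the total index score
#'
#' Cuts the total DHD-CVD score at the within-sex 1/3 and 2/3 empirical
#' quantiles. Assignment is half-open with ties at a cutpoint going to the
#' upper stratum: T1 below the first cutpoint, T2 at or above the first and
#' below the second, T3 at or above the second (the printed
#' "T2: >= cut1 - < cut2" convention).
#'
#' @param scores output of [score_index()], with `sex` and `total` columns.
#' @return `scores` with a `tertile` factor (`T1` < `T2` < `T3`) added;
#'   attribute `"cutpoints"` holds the per-sex cutpoints.
#' @export
assign_sex_specific_tertiles <- function(scores) {
  stopifnot(all(c("sex", "total") %in% names(scores)))
  scores <- tibble::as_tibble(scores)
  cuts <- list()
  tert <- character(nrow(scores))
  for (s in unique(as.character(scores$sex))) {
    idx <- which(as.character(scores$sex) == s)
    if (length(idx) < 3) stop("fewer than 3 patients of sex '", s, "'")
    x <- scores$total[idx]
    if (diff(range(x)) == 0) stop("degenerate tertiles: all scores identical for sex '", s, "'")
    q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    cuts[[s]] <- q
    tert[idx] <- ifelse(x < q[1], "T1", ifelse(x < q[2], "T2", "T3"))
  }
  scores$tertile <- factor(tert, levels = c("T1", "T2", "T3"))
  attr(scores, "cutpoints") <- cuts
  scores
}

#' Consumer / non-consumer flags
#'
#' Flags each patient as a consumer (intake strictly above zero) of legumes,
#' nuts and fish, and as a plant-sterol product user. Used for the
#' consumers-vs-non-consumers contrasts of low-intake components.
#'
#' @param intakes data frame with `patient_id`, `legumes`, `nuts_total`,
#'   `fish` and either `sterol_use` or `sterol_products`.
#' @return tibble of `patient_id` and logical `consumer_*` flags.
#' @export
derive_consumer_flags <- function(intakes) {
  intakes <- as.data.frame(intakes)
  sterol <- if ("sterol_use" %in% names(intakes)) {
    as.logical(intakes$sterol_use)
  } else {
    intakes$sterol_products > 0
  }
  tibble::tibble(
    patient_id = intakes$patient_id,
    consumer_legumes = intakes$legumes > 0,
    consumer_nuts = intakes$nuts_total > 0,
    consumer_fish = intakes$fish > 0,
    consumer_sterols = sterol
  )
}

#' Read / write a component ruleset as YAML
#'
#' The ruleset ships as a versioned YAML resource
#' (`system.file("extdata", "dhd_cvd_ruleset.yaml", package = "dhdkidney")`)
#' mirroring the [component_rule()] fields, so thresholds can be overridden
#' without code changes.
#'
#' @param path YAML file path.
#' @return [read_ruleset()]: a `dhd_ruleset`; [write_ruleset()]: `path`,
#'   invisibly.
#' @export
read_ruleset <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(r) do.call(component_rule, r))
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "dhd_ruleset")
}

#' @rdname read_ruleset
#' @param ruleset a `dhd_ruleset` to serialize.
#' @export
write_ruleset <- function(ruleset, path) {
  raw <- lapply(unname(ruleset), function(r) {
    r <- unclass(r)
    r[!vapply(r, is.null, logical(1))]
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
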
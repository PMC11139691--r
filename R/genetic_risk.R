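VALID_BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Palindromic (strand-ambiguous) SNP test
#'
#' A SNP is ambiguous when its allele pair is palindromic (A/T or C/G): the
#' strand cannot be resolved from the alleles alone, so such SNPs are
#' excluded from risk-score construction.
#'
#' @param effect_allele,other_allele single-character allele vectors.
#' @return logical vector.
#' @export
is_ambiguous <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!all(effect_allele %in% VALID_BASES) || !all(other_allele %in% VALID_BASES)) {
    stop("alleles must be A, C, G or T")
  }
  if (any(effect_allele == other_allele)) stop("effect and other allele identical")
  unname(BASE_COMPLEMENT[effect_allele] == other_allele)
}

#' Harmonize a GWAS SNP against cohort genotype alleles
#'
#' Determines how a cohort dosage (counted allele / other observed allele)
#' must be oriented to count the GWAS effect allele. Direct matching is
#' attempted first, then strand-complement matching; an allele pair that is
#' incompatible even after complementing is `unresolvable` and the SNP is
#' dropped. Orientations:
#'
#' * `as_is` -- counted allele equals the effect allele, use dosage d.
#' * `flip_dosage` -- counted equals the other allele, use 2 - d.
#' * `strand_flip_as_is` / `strand_flip_dosage` -- same after complementing
#'   the cohort alleles.
#'
#' @param effect_allele,other_allele GWAS alleles.
#' @param counted_allele,observed_other cohort alleles (dosage counts
#'   `counted_allele`).
#' @return character vector of orientations.
#' @export
harmonize <- function(effect_allele, other_allele, counted_allele, observed_other) {
  n <- max(lengths(list(effect_allele, other_allele, counted_allele, observed_other)))
  ea <- rep_len(toupper(effect_allele), n)
  oa <- rep_len(toupper(other_allele), n)
  ca <- rep_len(toupper(counted_allele), n)
  oo <- rep_len(toupper(observed_other), n)
  if (!all(c(ea, oa, ca, oo) %in% VALID_BASES)) stop("alleles must be A, C, G or T")
  cca <- BASE_COMPLEMENT[ca]
  coo <- BASE_COMPLEMENT[oo]
  out <- rep("unresolvable", n)
  out[ca == ea & oo == oa] <- "as_is"
  out[out == "unresolvable" & ca == oa & oo == ea] <- "flip_dosage"
  out[out == "unresolvable" & cca == ea & coo == oa] <- "strand_flip_as_is"
  out[out == "unresolvable" & cca == oa & coo == ea] <- "strand_flip_dosage"
  out
}

#' Re-orient GWAS weights towards higher CKD risk
#'
#' Flips each SNP's effect allele and weight sign jointly so that a positive
#' weight always reads "higher genetic risk of CKD". The magnitude of the
#' weight is preserved; applying the re-orientation twice is the identity.
#'
#' @param gwas tibble with `rsid`, `effect_allele`, `other_allele`, `weight`.
#' @return the tibble with negative-weight rows re-oriented.
#' @export
orient_risk <- function(gwas) {
  neg <- gwas$weight < 0
  ea <- gwas$effect_allele
  gwas$effect_allele[neg] <- gwas$other_allele[neg]
  gwas$other_allele[neg] <- ea[neg]
  gwas$weight[neg] <- -gwas$weight[neg]
  gwas
}

#' Select SNPs for the main and sub risk scores
#'
#' The main score (`set_all`) keeps non-ambiguous SNPs with p < `p_nominal`
#' (default 0.05); the genome-wide sub-score (`set_sub`) keeps non-ambiguous
#' SNPs with p < `p_genomewide` (default 5e-8). `set_sub` is always a subset
#' of `set_all`; palindromic SNPs are in neither.
#'
#' @param gwas tibble with `rsid`, `effect_allele`, `other_allele`, `p_value`.
#' @param p_nominal,p_genomewide selection thresholds.
#' @param exclude_ambiguous drop palindromic SNPs (default `TRUE`).
#' @return list with character vectors `set_all`, `set_sub`.
#' @export
select_snps <- function(gwas, p_nominal = 0.05, p_genomewide = 5e-8,
                        exclude_ambiguous = TRUE) {
  stopifnot(p_genomewide < p_nominal)
  if (anyNA(gwas$p_value)) stop("missing p-values in GWAS table")
  keep <- rep(TRUE, nrow(gwas))
  if (exclude_ambiguous) {
    keep <- !is_ambiguous(gwas$effect_allele, gwas$other_allele)
  }
  set_all <- gwas$rsid[keep & gwas$p_value < p_nominal]
  set_sub <- gwas$rsid[keep & gwas$p_value < p_genomewide]
  if (length(set_all) == 0) stop("SNP selection is empty at p < ", p_nominal)
  list(set_all = set_all, set_sub = set_sub)
}

#' Align cohort dosages with harmonized GWAS weights
#'
#' For each SNP shared between the GWAS table and the dosage matrix,
#' determines the orientation with [harmonize()], flips dosages (2 - d)
#' where the counted allele is the non-effect allele, and drops
#' unresolvable SNPs. Returns effect-allele dosages ready for
#' [compute_grs()] plus a tidy harmonization log.
#'
#' @param dosages a `dosage_matrix`: list with `dosages` (patients x SNPs
#'   matrix, rsids as colnames, patient ids as rownames), `counted_allele`
#'   and `other_allele` (named per rsid).
#' @param gwas GWAS tibble (`rsid`, `effect_allele`, `other_allele`,
#'   `weight`).
#' @param snps optional rsid subset (e.g. from [select_snps()]).
#' @return list with `dosages` (aligned matrix), `weights` (named numeric),
#'   `log` (tibble: rsid, action, reason).
#' @export
align_dosages <- function(dosages, gwas, snps = NULL) {
  rsids <- intersect(gwas$rsid, colnames(dosages$dosages))
  if (!is.null(snps)) rsids <- intersect(rsids, snps)
  if (length(rsids) == 0) stop("no overlapping SNPs between weights and dosages")
  g <- gwas[match(rsids, gwas$rsid), , drop = FALSE]
  orient <- harmonize(g$effect_allele, g$other_allele,
                      dosages$counted_allele[rsids], dosages$other_allele[rsids])
  log <- tibble::tibble(
    rsid = rsids,
    action = orient,
    reason = ifelse(orient == "unresolvable",
                    "allele pair incompatible after strand complement", "harmonized")
  )
  keep <- orient != "unresolvable"
  mat <- dosages$dosages[, rsids[keep], drop = FALSE]
  flip <- orient[keep] %in% c("flip_dosage", "strand_flip_dosage")
  mat[, flip] <- 2 - mat[, flip, drop = FALSE]
  list(dosages = mat,
       weights = stats::setNames(g$weight[keep], rsids[keep]),
       log = log)
}

#' Weighted genetic risk score
#'
#' Per-patient weighted sum of effect-allele dosages:
#' \eqn{GRS_i = \sum_j w_j d_{ij}} over the retained, harmonized SNPs.
#' Missing dosages are mean-imputed per SNP (the column mean, i.e. 2 x
#' allele frequency) with a message.
#'
#' @param dosages patients x SNPs matrix of effect-allele dosages in
#'   `[0, 2]` (e.g. `align_dosages()$dosages`).
#' @param weights named numeric weights (log-odds ratios per effect allele);
#'   names must cover the matrix columns.
#' @return named numeric vector of scores, one per patient.
#' @export
compute_grs <- function(dosages, weights) {
  snps <- colnames(dosages)
  if (is.null(snps) || !all(snps %in% names(weights))) {
    stop("dosage columns must be named and covered by weights")
  }
  if (length(snps) == 0) stop("no overlapping SNPs between weights and dosages")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (anyNA(dosages)) {
    message("mean-imputing missing dosages per SNP")
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
    }
  }
  drop(dosages %*% weights[snps])
}

#' Stratify a genetic risk score
#'
#' Tertiles or median split with the printed boundary convention for genetic
#' scores: lower stratum closed above (`<= cut`), upper stratum strictly
#' above (`> cut`) -- note this is the opposite openness to the diet-score
#' tertiles.
#'
#' @param scores numeric risk scores.
#' @param scheme `"tertiles"` or `"median_split"`.
#' @return factor of strata (`T1`/`T2`/`T3` or `low`/`high`) with attribute
#'   `"cutpoints"`.
#' @export
stratify_grs <- function(scores, scheme = c("tertiles", "median_split")) {
  scheme <- match.arg(scheme)
  if (diff(range(scores)) == 0) stop("degenerate score distribution")
  if (scheme == "tertiles") {
    if (length(scores) < 3) stop("need at least 3 scores for tertiles")
    q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    out <- factor(ifelse(scores <= q[1], "T1", ifelse(scores <= q[2], "T2", "T3")),
                  levels = c("T1", "T2", "T3"))
  } else {
    if (length(scores) < 2) stop("need at least 2 scores for a median split")
    q <- stats::median(scores)
    out <- factor(ifelse(scores > q, "high", "low"), levels = c("low", "high"))
  }
  attr(out, "cutpoints") <- q
  out
}

#' Build both genetic risk scores for a cohort
#'
#' Convenience wrapper: re-orients weights to the risk direction, selects
#' the nominal and genome-wide SNP sets, harmonizes dosages, computes
#' GRS_all and GRS_sub, and stratifies them (tertiles for GRS_all, median
#' split for GRS_sub).
#'
#' @param dosages a `dosage_matrix` (see [align_dosages()]).
#' @param gwas GWAS summary-statistics tibble (`rsid`, `effect_allele`,
#'   `other_allele`, `weight`, `p_value`).
#' @inheritParams select_snps
#' @return list with `grs` (tibble: patient_id, grs_all, grs_sub,
#'   stratum_all, stratum_sub), `n_snps` (per score), `log` (harmonization
#'   log).
#' @export
build_grs <- function(dosages, gwas, p_nominal = 0.05, p_genomewide = 5e-8) {
  gwas <- orient_risk(gwas)
  sel <- select_snps(gwas, p_nominal, p_genomewide)
  all_al <- align_dosages(dosages, gwas, sel$set_all)
  grs_all <- compute_grs(all_al$dosages, all_al$weights)
  sub_rsids <- intersect(sel$set_sub, colnames(all_al$dosages))
  grs_sub <- compute_grs(all_al$dosages[, sub_rsids, drop = FALSE], all_al$weights)
  tibble_out <- tibble::tibble(
    patient_id = rownames(dosages$dosages),
    grs_all = unname(grs_all),
    grs_sub = unname(grs_sub),
    stratum_all = stratify_grs(grs_all, "tertiles"),
    stratum_sub = stratify_grs(grs_sub, "median_split")
  )
  list(grs = tibble_out,
       n_snps = c(all = ncol(all_al$dosages), sub = length(sub_rsids)),
       log = all_al$log)
}
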
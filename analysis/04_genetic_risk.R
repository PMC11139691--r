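#!/usr/bin/env Rscript
# Genetic risk scores: harmonize GWAS weights against cohort dosages, build
# GRS_all (nominal SNPs, tertiles) and GRS_sub (genome-wide SNPs, median
# split).

suppressPackageStartupMessages(library(dhdkidney))

gwas <- utils::read.delim("results/cohort/gwas.tsv")
dos_tab <- utils::read.delim("results/cohort/dosages.tsv", check.names = FALSE)
alleles <- utils::read.delim("results/cohort/dosage_alleles.tsv")

dos <- as.matrix(dos_tab[-1])
rownames(dos) <- dos_tab$patient_id
dosages <- list(dosages = dos,
                counted_allele = setNames(alleles$counted_allele, alleles$rsid),
                other_allele = setNames(alleles$other_allele, alleles$rsid))

out <- build_grs(dosages, gwas)
cat(sprintf("GRS_all: %d SNPs, range %.3f to %.3f\n", out$n_snps["all"],
            min(out$grs$grs_all), max(out$grs$grs_all)))
cat(sprintf("GRS_sub: %d SNPs, range %.3f to %.3f\n", out$n_snps["sub"],
            min(out$grs$grs_sub), max(out$grs$grs_sub)))
print(table(out$grs$stratum_all))
print(table(out$grs$stratum_sub))
cat("Harmonization actions:\n")
print(table(out$log$action))

utils::write.table(as.data.frame(out$grs), "results/grs.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(as.data.frame(out$log), "results/grs_harmonization_log.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
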
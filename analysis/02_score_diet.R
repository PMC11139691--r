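#!/usr/bin/env Rscript
# Score the DHD-CVD index: plausibility filter, 15 component scores, total,
# sex-specific tertiles and consumer flags.

suppressPackageStartupMessages(library(dhdkidney))

intake <- utils::read.delim("results/cohort/intake.tsv")

pf <- apply_plausibility_filter(intake)
cat(sprintf("Energy plausibility filter: %d kept, %d excluded\n",
            nrow(pf$kept), nrow(pf$excluded)))

scores <- score_index(pf$kept)
scores <- assign_sex_specific_tertiles(scores)
flags <- derive_consumer_flags(pf$kept)

cat(sprintf("Total DHD-CVD score: mean %.1f, SD %.1f (theoretical range 0-150)\n",
            mean(scores$total), sd(scores$total)))
cuts <- attr(scores, "cutpoints")
cat(sprintf("Tertile cutpoints: women %.1f / %.1f, men %.1f / %.1f\n",
            cuts$female[1], cuts$female[2], cuts$male[1], cuts$male[2]))
comp_medians <- vapply(scores[grep("^score_", names(scores))], median, numeric(1))
cat("Median component scores:\n")
print(round(comp_medians, 2))

dir.create("results", showWarnings = FALSE)
out <- dplyr::left_join(scores, flags, by = "patient_id")
utils::write.table(as.data.frame(out), "results/scores.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
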
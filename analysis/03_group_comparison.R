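#!/usr/bin/env Rscript
# Group descriptives with Mann-Whitney / chi-square p-values for every PFT
# and lung-density index of the simulated cohort (the layout of a clinical
# "patient characteristics" table). Reads results/cohort.csv.

suppressPackageStartupMessages(library(lungdens))
tab <- read_cohort("results/cohort.csv")

report <- build_report(tab)
t1 <- report$group_comparison
write.csv(t1, "results/table_group_comparison.csv", row.names = FALSE)

sig <- t1$variable[!is.na(t1$p_value) & t1$p_value < 0.05]
cat("variables separating the groups at alpha = 0.05:\n")
cat(paste(" ", sig, collapse = "\n"), "\n")
ldis <- intersect(c("EXP_MLD_HU", "MLDD_HU", "EI_MLD_pct", "EI_Volume_pct",
                    "E900_pct", "E850_pct"), sig)
cat(sprintf("%d of the 6 headline density indices reject\n", length(ldis)))
cat("wrote results/table_group_comparison.csv\n")
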
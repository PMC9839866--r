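#!/usr/bin/env Rscript
# Region structure and sequence features of the deduplicated cohort:
# N/H/C lengths, per-region residue composition, N-region charge, compound
# hydrophobicity scores, (-3,-1) motif classes and a conservation profile
# over the modal SP length.

suppressPackageStartupMessages(library(sigpepR))

tab <- read_sp_table("results/data/annotations.tsv")
dd <- dedupe(tab)
cohort <- dd$cohort
cat(sprintf("%d rows read, %d duplicates removed, %d unique SPs\n",
            nrow(tab), dd$n_removed, nrow(cohort)))

decomp <- decompose_cohort(cohort)      # table boundaries take precedence
features <- sp_feature_table(cohort, decomp)
comp <- region_composition(cohort, decomp)
ld <- length_distributions(cohort, decomp)

cat(sprintf("C-region of exactly 5 residues: %.1f%% of SPs\n",
            100 * ld$frac_c5))
pos <- sum(comp$count[comp$region == "N" & comp$aa %in% c("K", "R", "H")])
cat(sprintf("N-region positive share %.2f%% (Arg+Lys %.2f%% of positives)\n",
            100 * pos / sum(comp$count[comp$region == "N"]),
            100 * sum(comp$count[comp$region == "N" &
                                   comp$aa %in% c("K", "R")]) / pos))
cat(sprintf("H-region Leu %.2f%%; C-region Ala %.2f%%\n",
            100 * comp$fraction[comp$region == "H" & comp$aa == "L"],
            100 * comp$fraction[comp$region == "C" & comp$aa == "A"]))
cat(sprintf("motif classes: %.1f%% AXA, %.1f%% VXA, %.1f%% other\n",
            100 * mean(features$motif_class == "AXA"),
            100 * mean(features$motif_class == "VXA"),
            100 * mean(features$motif_class == "OTHER")))

lens <- nchar(cohort$sp_seq)
modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
logo <- data.frame(position = seq_len(modal),
                   bits = positional_information(cohort$sp_seq[lens == modal]))
cat(sprintf("conservation profile over the %d SPs of modal length %d\n",
            sum(lens == modal), modal))

write_report(list(decomp = decomp, features = features, composition = comp,
                  length_total = ld$total, length_n = ld$n, length_h = ld$h,
                  length_c = ld$c, logo = logo),
             "results/region_features")
cat("tables written to results/region_features\n")
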
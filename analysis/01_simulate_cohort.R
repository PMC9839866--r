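#!/usr/bin/env Rscript
# Generate the reference-emulation cohort: 352 annotated signal peptides of
# which 30 duplicate an earlier sequence, plus SP coding sequences, a
# 400-ORF reference ORFeome and per-SP mature-prefix context for the fusion
# analysis. All later steps read the files written here.

suppressPackageStartupMessages(library(sigpepR))

seed <- as.integer(Sys.getenv("SP_SEED", "1"))
out <- "results/data"

params <- synth_params(n_sps = 352L, n_duplicates = 30L, seed = seed)
files <- generate_cohort(params, out, n_orfs = 400L, len_codons = 250L)
tab <- attr(files, "sp_table")

cat(sprintf("cohort: %d SPs (%d unique sequences), seed %d\n",
            nrow(tab), length(unique(tab$sp_seq)), seed))
cat(sprintf("SP length range: %d-%d residues, median %d\n",
            min(nchar(tab$sp_seq)), max(nchar(tab$sp_seq)),
            as.integer(stats::median(nchar(tab$sp_seq)))))
cat(sprintf("planted motif classes: %.1f%% AXA, %.1f%% VXA\n",
            100 * mean(tab$true_motif_class == "AXA"),
            100 * mean(tab$true_motif_class == "VXA")))
cat("files:\n")
for (f in unlist(files)) cat(" ", f, "\n")
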
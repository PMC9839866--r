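#!/usr/bin/env Rscript
# Synonymous codon usage of SP coding regions against the whole ORFeome:
# per-codon SP fraction vs All fraction, their difference, and the
# rare-codon share of the SP coding sequences.

suppressPackageStartupMessages(library(sigpepR))

cohort <- dedupe(read_sp_table("results/data/annotations.tsv"))$cohort
orfeome <- read_cds_fasta("results/data/orfeome.fasta")

sp_tab <- codon_fractions(cohort$sp_cds)
all_tab <- codon_fractions(orfeome$bases)
delta <- compare_fractions(sp_tab, all_tab)

cat(sprintf("codons counted: %d (SP regions), %d (ORFeome)\n",
            attr(sp_tab, "n_codons"), attr(all_tab, "n_codons")))

top <- delta[order(-abs(delta$delta)), ][1:10, ]
cat("largest SP-vs-ORFeome codon fraction differences:\n")
print(top, row.names = FALSE, digits = 3)

share_sp <- rare_codon_share(cohort$sp_cds, all_tab)
share_all <- rare_codon_share(orfeome$bases, all_tab)
cat(sprintf("rare-codon share: %.3f in SP coding regions vs %.3f genome-wide\n",
            share_sp, share_all))

write_report(list(codon_sp = sp_tab, codon_all = all_tab,
                  codon_delta = delta,
                  rare_share = data.frame(set = c("sp", "orfeome"),
                                          share = c(share_sp, share_all))),
             "results/codon_bias")
cat("tables written to results/codon_bias\n")
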
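# sigpepR

Cohort-scale analysis of secretory **signal peptides (SPs)** — the short
N-terminal leaders that route nascent proteins into the endoplasmic
reticulum and are cleaved off by signal peptidase. The package targets the
kind of genome-wide SP survey done for *Saccharomyces cerevisiae*: given a
table of annotated SPs (sequence, cleavage position, optional N/H/C region
boundaries, optional secretion titers) plus coding sequences, it computes
the sequence features that predict secretion efficiency and the cohort
summaries used to derive secretion rules. It is written for protein
secretion / cell-factory researchers who want those analyses reproducible
and testable rather than spread across web servers.

## What it computes

* **N/H/C region decomposition.** When a table provides no boundaries, a
  deterministic hydropathy heuristic finds the hydrophobic H-core: seed at
  the best mean Kyte–Doolittle window (length `min(7, len − 3)`), extend
  while adjacent residues have KD ≥ 1.0, clip so the N-region keeps ≥ 1 and
  the C-region ≥ 2 residues.
* **Hydropathy profiles and the compound score.** Sliding window mean of
  the Kyte–Doolittle scale (window 9); the compound hydrophobicity score is
  `max window mean × H-region length`. Scores of 23–24 mark an empirically
  unfavourable band; the per-residue window mean classifies translocation
  bias (≤ 1.75 post-translational / Sec-dependent, ≥ 1.81 SRP-biased).
* **(−3,−1) cleavage motifs.** AXA (Ala at −3 and −1) and VXA (Val at −3,
  Ala at −1) classes at the cleavage site, per the signal-peptidase
  (−3,−1) rule.
* **Fusion-induced cleavage shifts.** A transparent log-odds site weight
  matrix over positions −3…+2 around the cleavage bond, trained on the
  cohort, re-predicts each SP's cleavage site after grafting onto a new
  mature protein and flags shifted sites.
* **Codon bias.** Per-family synonymous codon fractions of SP coding
  regions vs the whole ORFeome, their per-codon difference, and a
  rare-codon share under a within-family quantile rule.
* **Cohort statistics.** Deduplication, chromosome distribution,
  region-length histograms, per-position information content (sequence-logo
  bits), titer means per feature category, and a ranked seven-rule
  secretion report (N = 5, H ∈ 8–9, C = 5, net N-charge +1, AXA/VXA motif,
  score outside 23–24, no fusion shift).
* **Synthetic cohorts.** A fully parameterised generator
  (`synth_params()`, `simulate_cohort()`) that emulates the reference
  cohort's region-length distributions, composition, motif frequencies,
  codon bias and a feature-conditioned log-normal titer model — every
  configured quantity is recoverable by the corresponding analysis stage,
  which is what the test suite checks.

## Worked example

```r
library(sigpepR)

sp <- "MRFPSIFTAVLFAASSALA"        # the alpha-factor pre-region
(d <- decompose_regions(sp))
#> $n_len 5   $h_len 9   $c_len 5   $flagged FALSE

compound_score(sp, d$h_len)
#> $max_window_mean 2.533  $h_len 9  $score 22.8

classify_c_motif(sp)
#> $triplet "ALA"  $klass "AXA"

n_region_charge(sp, d$n_len)$charge
#> 1
classify_translocation_bias(2.533)
#> "srp_biased"
```

So the α-factor leader decomposes into a 5-residue N-region carrying one
positive charge, a 9-residue hydrophobic core and a 5-residue C-region
ending in an AXA motif; its compound score of 22.8 sits just below the
unfavourable 23–24 band, and its per-residue hydrophobicity (2.53) puts it
on the SRP/co-translational side of the translocation split — all features
the cohort analysis associates with efficient secretion.

The `analysis/` directory holds the numbered workflow
(`01_simulate_cohort.R` … `05_cohort_summary.R`): generate the
reference-emulation cohort (352 SPs, 30 duplicated sequences), then region
features, cleavage-shift detection, codon bias and cohort summaries, each
writing its tables under `results/`.

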
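---
title: "Methods: signal-peptide cohort analysis and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-peptide cohort analysis and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpepR)
```

## The analysis model

A signal peptide (SP) is modelled as three contiguous regions: a charged
amino-terminal N-region, a hydrophobic H-core and a polar C-region that
ends at the cleavage bond. All positions are 1-based; `cleavage_pos` is the
index of the *last* SP residue, so the (−1) position of the (−3,−1)
cleavage rule is `cleavage_pos` itself and the mature protein starts at
`cleavage_pos + 1`.

### Region decomposition

When an annotation table carries `n_end`/`h_end` boundaries they are used
as-is — cohort statistics on an annotated table reflect its annotations,
never the heuristic. Otherwise `decompose_regions()` applies a
deterministic hydropathy rule:

1. seed the H-core at the contiguous window of length `min(7, len − 3)`
   with the highest mean Kyte–Doolittle (KD) value, leftmost on ties;
2. extend left and right while the adjacent residue has KD ≥ 1.0;
3. clip so `n_len ≥ 1` and `c_len ≥ 2`, moving the H edge nearer the
   violated bound.

The seed length 7, the extension threshold 1.0 and the leftmost tie-break
are fixed constants of the method (exposed as arguments) so every
downstream number is reproducible. The thresholds were chosen once from
the structure of the KD scale: 1.0 separates the strongly hydrophobic
residues (A, M, C, F, L, V, I) from everything else, and a 7-residue seed
is the longest window guaranteed to fit a minimal 6-residue SP with the
mandatory flanks. If no window has a non-negative mean the sequence has no
hydrophobic core; the decomposition is returned flagged with the H-core
fixed at the seed window (still clipped, since the partition invariants
hold for every output) and a warning is emitted. Sequences shorter than 6
residues are rejected.

### Hydropathy features

`kd_window_profile()` computes arithmetic window means of the published KD
scale (window 9, shrunk to the sequence length when shorter). Two derived
statistics deliberately live on different scales and are never merged:

* the **compound score** `max window mean × h_len` (typical range ~10–40),
  whose 23–24 band marks empirically unfavourable secretion;
* the **per-residue max window mean** (~−4…4.5), thresholded at ≤ 1.75 /
  ≥ 1.81 to classify post-translational vs SRP-biased translocation.

Both the band and the thresholds are arguments with those defaults.
`'X'` residues are accepted in input but excluded from all hydropathy and
composition statistics, with a warning at parse time.

### Charge, composition, conservation

N-region net charge counts K, R **and H** as +1 and D, E as −1. Histidine
is included because the cohort statistic "Arg+Lys make up ~88% of
positives" presupposes a third positive class; the free N-terminal amine
is not counted. Per-region composition pools residue counts across the
cohort and normalises within region (sums checked to 1 ± 1e−9).
Conservation is per-position information content over equal-length
sequences, `log2 20 + Σ p·log2 p` in bits, with no small-sample
correction — at cohort sizes of hundreds of sequences the correction term
is below the reporting resolution, and leaving it out keeps the statistic
a closed form.

### Cleavage-site matrix and fusion shifts

The cleavage model is a position-specific log-odds matrix over the five
slots −3, −2, −1, +1, +2 around the bond (cleavage-site numbering has no
slot 0). Foreground frequencies are Laplace-smoothed
(`(count + pc)/(n + 20·pc)`, default `pc = 1`); the background is the
residue frequency over all fused training sequences smoothed with the
pseudocount scaled to its sample size (`s = pc·total/n`), so a residue
observed nowhere scores exactly 0 instead of inheriting a spurious
log-odds from asymmetric smoothing. Re-prediction scores every candidate
cleavage position within ±5 of the native site (clamped to
`[4, len − 2]`) and takes the argmax, leftmost on ties — which keeps the
native site against an equal downstream competitor. This matrix is a
transparent stand-in for a learned cleavage predictor: absolute shifted
counts are soft quantities, and the tests treat them as rates with
binomial error, not as exact targets.

### Codon bias

Codon fractions are pooled counts normalised within each synonymous family
of the standard nuclear code; stop codons are excluded (internal stops
with a warning), as are codons containing ambiguous bases. "Rare" is a
within-family rule: reference fraction strictly below the family's 0.25
quantile (single-codon families contribute nothing). The quantile is a
parameter; a fixed external codon-usage table can be supplied as the
reference instead of an ORFeome.

### Cohort summaries

Deduplication is exact string identity of the SP sequence, first
occurrence kept — duplicate SPs arise from paralogous genes and would
otherwise be double-counted in secretion statistics. Score-bin categories
round the compound score half-away-from-zero to integers. The seven-rule
report flags `n_len = 5`, `h_len ∈ {8, 9}`, `c_len = 5`, net charge +1,
AXA/VXA motif, score outside [23, 24] and no fusion shift; ranking is by
rule count then compound score (the tie-break is plumbing for a
deterministic report, nothing more). Category titer means include
zero-titer SPs and exclude only missing titers, which are counted
separately.

## The synthetic cohort generator

`synth_params()` fixes the study conditions; `simulate_cohort()` draws
from them through a single RNG stream keyed by `seed` (the caller's RNG
state is restored afterwards). Defaults:

* **Region lengths.** N over 2–20 residues, mode 5, long right tail; H
  over 6–14, mode 9; C over 3–8 with 64.38% of mass on 5.
* **Composition targets** (observed fractions, not raw draw weights):
  N-region positive share 22.37% with Arg+Lys 87.86% of positives;
  H-region Leu 26.59%; C-region Ala 23.26%. The constructor inverts two
  distortions analytically: the forced initiator Met dilutes the N-region
  draw (positives are scaled by `mean_n/(mean_n − 1)`), and motif planting
  overwrites the −3/−1 positions (the C-region Ala draw probability is
  solved by `uniroot` so the *observed* Ala share hits the target).
* **Motifs and shifts.** AXA planted with p = 0.199, VXA with 0.211.
  Fusion shifts (overall rate 0.11) are planted only inside the OTHER
  motif class — consistent with shifted SPs having inefficient native
  motifs — so the marginal motif frequencies are untouched; the native
  −3/−1 is redrawn from the non-Ala C alphabet and a strong A-x-A site is
  planted five residues into the mature prefix.
* **Mature prefix.** Ten residues drawn from an acidic/basic junction
  alphabet (D/E/K/W) disjoint from the polar C-region alphabet. This makes
  the +1/+2 slots a sharp positional anchor for the site matrix, so the
  planted downstream site is the only credible competitor. A real mature
  protein shares more alphabet with C-regions; shift detection on real
  fusions is accordingly noisier than on this test-bed.
* **Codon model.** Within each synonymous family, baseline weights
  proportional to k…1 over alphabetically ordered codons; SP coding
  regions multiply below-quantile (rare) codons by 2.5 and renormalise,
  emulating the rare-codon enrichment of SP sequences without claiming its
  mechanism.
* **Titers.** `base_titer` 4106 U L⁻¹; multipliers ×1.3 (AXA/VXA motif),
  ×1.2 (net charge +1), ×0.51 (shifted), ×0.7 (score in 23–24); mean-one
  log-normal noise `exp(σZ − σ²/2)` with σ = 0.3, so σ = 0 reproduces the
  deterministic product exactly. Because the multipliers sit on top of the
  base, the raw population mean would exceed 4106 by the mean multiplier
  (~9%); `simulate_cohort()` therefore rescales by the realized mean
  multiplier (`calibrate_mean`, on by default) so the *cohort mean* is
  centred on 4106 — the quantity the reference value describes —
  while every multiplier ratio, the recoverable quantity, is unchanged.
* **Uniqueness and duplicates.** SP sequences are unique by rejection
  sampling (100 retries); `n_duplicates` rows then reuse an earlier
  sequence under a new gene id with a fresh titer draw, emulating
  paralogous duplicate SPs (352 rows / 30 duplicates in the reference
  configuration).
* **Strong-structure mode** draws H from {L, I, V, F} (KD ≥ 2.8) and the
  flanks from KD ≤ 0 alphabets with no motif planting; it exists to
  measure boundary recovery of the decomposition heuristic under
  conditions where the true boundary is unambiguous.

What the generator does **not** emulate: real H-regions with marginal
hydrophobicity (where SignalP-style decompositions are genuinely
ambiguous), correlated residues within a region (draws are iid),
pre-pro leaders, biased codon context effects, or any cell-physiology
coupling between SPs and titers beyond the four flag multipliers. Passing
parameter-recovery tests therefore validates the *analysis machinery*, not
the biological accuracy of any particular annotation.

## Problem sizes and tolerances

The test suite generates cohorts of 150–2000 SPs per module test, a
5000-SP cohort for the motif/shift/titer recovery checks, a 400-SP
strong-structure cohort for boundary recovery, and 10⁵ codons for codon
recovery — sizes at which every configured rate is resolvable against its
sampling error while the whole suite runs in about a minute. Statistical
assertions use a-priori sampling bands: 3 binomial SDs for proportions,
2 delta-method SEs for mean ratios, 4 SDs where a maximum over ~100
entries is tested (matrix weights, 61 codon fractions). Exact identities
(normalisations, partitions, round-trips) use 1e−9 or exact equality.

## Known limitations

* The decomposition heuristic is a fixed stand-in for HMM-based N/H/C
  annotation; on weakly hydrophobic SPs, where model-based annotators
  are themselves uncertain, its boundaries are one deterministic choice
  among several defensible ones.
* The site matrix ignores dependencies between positions and any
  influence beyond −3…+2; shifted-site counts are rate-level quantities.
* Only the standard nuclear genetic code is supported.
* The seven-rule report treats rules as independent booleans; no
  interaction or weighting is estimated.
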
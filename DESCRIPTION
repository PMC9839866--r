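Package: sigpepR
Title: Genome-Wide Signal Peptide Feature Analysis for Yeast Secretion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cohort-level analysis of secretory signal peptides (SPs):
    deterministic N/H/C region decomposition from Kyte-Doolittle hydropathy,
    per-region residue composition and charge, windowed hydropathy profiles and
    the compound hydrophobicity score (max window mean times H-region length),
    (-3,-1) cleavage-motif classification (AXA/VXA), a log-odds site weight
    matrix for detecting fusion-induced cleavage-site shifts, synonymous
    codon-usage comparison of SP coding regions against a whole ORFeome,
    positional information content for sequence logos, secretion-rule scoring,
    and a fully parameterised synthetic cohort generator so every stage is
    testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
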
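# Sense codons of the standard nuclear genetic code, grouped by amino acid.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' Synonymous codon fractions of a CDS set
#'
#' Pools codon counts over a set of coding sequences and normalises within
#' each synonymous family (per encoded amino acid). Stop codons are excluded
#' (internal stops with a warning); codons containing non-ACGT bases are
#' excluded with a warning.
#'
#' @param cds Character vector of DNA coding sequences, each with length
#'   divisible by 3.
#' @return `data.frame` over all 61 sense codons: `aa`, `codon`, `count`,
#'   `fraction` (NA for families with no observed codons), plus attribute
#'   `n_codons` (total sense codons counted).
#' @export
codon_fractions <- function(cds) {
  if (length(cds) == 0L) stop("empty CDS set", call. = FALSE)
  cds <- toupper(cds)
  if (any(nchar(cds) %% 3L != 0L)) {
    stop("CDS length not divisible by 3", call. = FALSE)
  }
  codons <- unlist(lapply(cds, function(s) {
    substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  }))
  ambiguous <- grepl("[^ACGT]", codons)
  if (any(ambiguous)) {
    warning(sprintf("%d codon(s) with ambiguous bases excluded",
                    sum(ambiguous)), call. = FALSE)
    codons <- codons[!ambiguous]
  }
  code <- sense_codons()
  gc_full <- Biostrings::GENETIC_CODE
  is_stop <- gc_full[codons] == "*"
  if (any(is_stop)) {
    # count stops that are not sequence-terminal as internal
    warning(sprintf("%d stop codon(s) excluded", sum(is_stop)), call. = FALSE)
    codons <- codons[!is_stop]
  }
  counts <- table(factor(codons, levels = names(code)))
  tab <- data.frame(aa = unname(code), codon = names(code),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  fam_tot <- tapply(tab$count, tab$aa, sum)
  tot <- as.numeric(fam_tot[tab$aa])
  tab$fraction <- ifelse(tot > 0, tab$count / tot, NA_real_)
  tab <- tab[order(tab$aa, tab$codon), ]
  rownames(tab) <- NULL
  attr(tab, "n_codons") <- sum(tab$count)
  tab
}

#' Compare codon fractions of two CDS sets
#'
#' Per-codon difference `sp_fraction - all_fraction`; deltas within a
#' synonymous family sum to 0 (when both families are observed).
#'
#' @param sp_table Codon fraction table of the SP coding regions.
#' @param all_table Codon fraction table of the reference (whole-ORFeome)
#'   set.
#' @return `data.frame` with `aa`, `codon`, `sp_fraction`, `all_fraction`,
#'   `delta`.
#' @export
compare_fractions <- function(sp_table, all_table) {
  stopifnot(identical(sp_table$codon, all_table$codon))
  data.frame(aa = sp_table$aa, codon = sp_table$codon,
             sp_fraction = sp_table$fraction,
             all_fraction = all_table$fraction,
             delta = sp_table$fraction - all_table$fraction,
             stringsAsFactors = FALSE)
}

# Rare codons under the within-family quantile rule: reference fraction
# strictly below the rare_quantile quantile of its synonymous family
# (families of size 1 contribute none).
rare_codon_set <- function(reference_table, rare_quantile = 0.25) {
  rare <- character(0)
  for (aa in unique(reference_table$aa)) {
    fam <- reference_table[reference_table$aa == aa, ]
    if (nrow(fam) < 2L || anyNA(fam$fraction)) next
    q <- stats::quantile(fam$fraction, rare_quantile, names = FALSE)
    rare <- c(rare, fam$codon[fam$fraction < q])
  }
  rare
}

#' Rare-codon share of SP coding sequences
#'
#' A codon is "rare" when its reference (whole-ORFeome) fraction lies
#' strictly below the `rare_quantile` quantile of the fractions in its
#' synonymous family; single-codon families contribute no rare codons.
#' Returns the fraction of SP sense codons that are rare.
#'
#' @param sp_cds Character vector of SP coding sequences.
#' @param reference_table Codon fraction table of the reference ORFeome.
#' @param rare_quantile Quantile defining "rare" (default 0.25).
#' @return Fraction in `[0, 1]`.
#' @export
rare_codon_share <- function(sp_cds, reference_table, rare_quantile = 0.25) {
  rare <- rare_codon_set(reference_table, rare_quantile)
  sp_tab <- suppressWarnings(codon_fractions(sp_cds))
  total <- sum(sp_tab$count)
  if (total == 0L) return(0)
  sum(sp_tab$count[sp_tab$codon %in% rare]) / total
}
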
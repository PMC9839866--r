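#' Remove duplicate SP sequences from a cohort
#'
#' Uniqueness is exact string identity of `sp_seq`; the first occurrence is
#' kept and row order is preserved. Idempotent.
#'
#' @param sp_table SP table.
#' @return List with `cohort` (unique rows) and `n_removed`.
#' @export
dedupe <- function(sp_table) {
  dup <- duplicated(sp_table$sp_seq)
  cohort <- sp_table[!dup, , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, n_removed = sum(dup))
}

#' Percentage of SP-containing genes per chromosome
#'
#' @param sp_table SP table with a `chromosome` column.
#' @param genes_per_chromosome Named integer vector (or two-column data
#'   frame `chromosome`, `n_genes`) of total gene counts per chromosome.
#' @return `data.frame` with `chromosome`, `n_sp`, `n_genes`, `pct`,
#'   covering every chromosome in `genes_per_chromosome` (0% where no SP
#'   gene maps).
#' @export
chromosome_distribution <- function(sp_table, genes_per_chromosome) {
  if (is.data.frame(genes_per_chromosome)) {
    gpc <- stats::setNames(genes_per_chromosome$n_genes,
                           genes_per_chromosome$chromosome)
  } else {
    gpc <- genes_per_chromosome
  }
  if (any(gpc <= 0)) stop("chromosome with zero genes", call. = FALSE)
  chroms <- sp_table$chromosome[!is.na(sp_table$chromosome)]
  unknown <- setdiff(unique(chroms), names(gpc))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown chromosome label '%s'", unknown[1L]), call. = FALSE)
  }
  n_sp <- as.integer(table(factor(chroms, levels = names(gpc))))
  data.frame(chromosome = names(gpc), n_sp = n_sp,
             n_genes = as.integer(gpc),
             pct = 100 * n_sp / as.integer(gpc),
             stringsAsFactors = FALSE)
}

#' Length distributions of SPs and their regions
#'
#' Integer-binned counts and fractions for the total SP length and the N/H/C
#' region lengths, plus the headline fraction of 5-residue C-regions.
#'
#' @param sp_table SP table.
#' @param decomp Row-aligned decomposition table.
#' @return List of data frames `total`, `n`, `h`, `c` (columns `length`,
#'   `count`, `fraction`) and the scalar `frac_c5`.
#' @export
length_distributions <- function(sp_table, decomp) {
  stopifnot(nrow(sp_table) == nrow(decomp))
  hist_of <- function(x) {
    t0 <- table(x)
    data.frame(length = as.integer(names(t0)), count = as.integer(t0),
               fraction = as.numeric(t0) / length(x))
  }
  list(total = hist_of(nchar(sp_table$sp_seq)),
       n = hist_of(decomp$n_len),
       h = hist_of(decomp$h_len),
       c = hist_of(decomp$c_len),
       frac_c5 = mean(decomp$c_len == 5L))
}

#' Round half away from zero
#'
#' Integer binning used for compound-score categories.
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Mean secretion titer per category
#'
#' Arithmetic mean and SD of titers per category label; SPs without a titer
#' are excluded from the means and counted separately (attribute
#' `n_no_titer`). Categories with no titered SP are suppressed with a
#' warning.
#'
#' @param sp_table SP table with a `titer` column.
#' @param categories Vector of category labels, row-aligned with
#'   `sp_table`.
#' @return `data.frame` with `category`, `n`, `mean_titer`, `sd_titer`.
#' @export
category_means <- function(sp_table, categories) {
  stopifnot(nrow(sp_table) == length(categories))
  has <- !is.na(sp_table$titer)
  if (!any(has)) stop("no titers in cohort", call. = FALSE)
  cat_all <- as.character(categories)
  labels <- unique(cat_all)
  rows <- lapply(labels, function(lab) {
    sel <- has & cat_all == lab
    if (!any(sel)) {
      warning(sprintf("category '%s' has no titered SPs; suppressed", lab),
              call. = FALSE)
      return(NULL)
    }
    t <- sp_table$titer[sel]
    data.frame(category = lab, n = length(t), mean_titer = mean(t),
               sd_titer = stats::sd(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_no_titer") <- sum(!has)
  rownames(out) <- NULL
  out
}

#' Secretion-rule report
#'
#' Scores every SP against the seven empirically favourable-secretion rules:
#' N-region of 5 residues, H-region of 8-9, C-region of 5, N-region net
#' charge exactly +1, AXA/VXA (-3,-1) motif, compound score outside the
#' unfavourable 23-24 band, and no fusion-induced cleavage shift. SPs are
#' ranked by rule count (descending), ties broken by compound score
#' (descending).
#'
#' @param features Feature table from [sp_feature_table()].
#' @param shifted Logical vector of fusion-shift flags, row-aligned.
#' @param bad_band Inclusive score band, default `c(23, 24)`.
#' @return `data.frame` with the seven logical flags, `rule_count` and
#'   `rank`, ordered by rank.
#' @export
rule_report <- function(features, shifted, bad_band = c(23, 24)) {
  stopifnot(nrow(features) == length(shifted))
  flags <- data.frame(
    gene_id = features$gene_id,
    n_len_5 = features$n_len == 5L,
    h_len_8_9 = features$h_len %in% c(8L, 9L),
    c_len_5 = features$c_len == 5L,
    n_charge_plus1 = features$n_charge == 1L,
    motif_axa_vxa = features$motif_class %in% c("AXA", "VXA"),
    score_outside_band = !(features$compound_score >= bad_band[1] &
                             features$compound_score <= bad_band[2]),
    not_shifted = !shifted,
    stringsAsFactors = FALSE)
  flags$rule_count <- rowSums(flags[, -1L])
  flags$compound_score <- features$compound_score
  ord <- order(-flags$rule_count, -flags$compound_score)
  flags <- flags[ord, ]
  flags$rank <- seq_len(nrow(flags))
  rownames(flags) <- NULL
  flags
}
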
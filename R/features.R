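#' Compound hydrophobicity score
#'
#' The score used to summarise an SP's hydrophobic core: the maximum
#' 9-residue window mean of the Kyte-Doolittle profile over the whole SP,
#' multiplied by the H-region length.
#'
#' @param sp_seq SP amino-acid string.
#' @param h_len H-region length in residues.
#' @param window Hydropathy window (default 9).
#' @return List with `max_window_mean`, `h_len` and `score`.
#' @export
compound_score <- function(sp_seq, h_len, window = 9L) {
  stopifnot(h_len >= 1L)
  m <- max_window_mean(sp_seq, window)
  list(max_window_mean = m, h_len = as.integer(h_len), score = m * h_len)
}

#' N-region net charge
#'
#' Net charge of the first `n_len` residues, counting K, R and H as +1
#' (histidine counted as positive) and D, E as -1. The positive-residue
#' count is returned alongside.
#'
#' @param sp_seq SP amino-acid string.
#' @param n_len N-region length.
#' @return List with integer `charge` and `n_positive`.
#' @export
n_region_charge <- function(sp_seq, n_len) {
  res <- split_residues(substr(sp_seq, 1L, n_len), "N-region")
  pos <- sum(res %in% c("K", "R", "H"))
  neg <- sum(res %in% c("D", "E"))
  list(charge = pos - neg, n_positive = pos)
}

#' Pooled per-region residue composition of a cohort
#'
#' Counts residues per region (N/H/C) across all SPs and normalises within
#' each region. 'X' residues are excluded.
#'
#' @param sp_table SP table.
#' @param decomp Decomposition table from [decompose_cohort()], row-aligned
#'   with `sp_table`.
#' @return `data.frame` with columns `region`, `aa`, `count`, `fraction`
#'   (all 20 residues per region, zero counts included).
#' @export
region_composition <- function(sp_table, decomp) {
  if (nrow(sp_table) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(nrow(sp_table) == nrow(decomp))
  counts <- matrix(0L, nrow = 3L, ncol = length(AA20),
                   dimnames = list(c("N", "H", "C"), AA20))
  for (i in seq_len(nrow(sp_table))) {
    res <- split_residues(sp_table$sp_seq[i], sprintf("row %d sp_seq", i))
    nl <- decomp$n_len[i]; hl <- decomp$h_len[i]
    regs <- rep(c("N", "H", "C"), c(nl, hl, length(res) - nl - hl))
    keep <- res != "X"
    t0 <- table(factor(regs[keep], levels = c("N", "H", "C")),
                factor(res[keep], levels = AA20))
    counts <- counts + as.matrix(t0)
  }
  frac <- counts / rowSums(counts)
  data.frame(region = rep(rownames(counts), each = length(AA20)),
             aa = rep(AA20, times = 3L),
             count = as.integer(t(counts)),
             fraction = as.numeric(t(frac)),
             stringsAsFactors = FALSE)
}

#' Per-position information content of equal-length sequences
#'
#' Sequence-logo style conservation: for each position, information in bits
#' is `log2(20) + sum(p * log2(p))` over the observed residue frequencies
#' (no small-sample correction). 'X' residues are excluded from the counts.
#'
#' @param seqs Character vector of >= 2 amino-acid strings, all the same
#'   length.
#' @return Numeric vector of bits, one per position.
#' @export
positional_information <- function(seqs) {
  stopifnot(is.character(seqs))
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    split_residues(seqs[i], sprintf("sequence %d", i))
  }))
  apply(mat, 2L, function(col) {
    col <- col[col != "X"]
    p <- as.numeric(table(col)) / length(col)
    log2(20) + sum(p * log2(p))
  })
}

#' Classify the (-3,-1) cleavage motif of an SP
#'
#' The triplet is taken at positions `cleavage_pos - 2 .. cleavage_pos`
#' (i.e. -3, -2, -1 counting back from the cleavage bond). AXA requires Ala
#' at both -3 and -1; VXA requires Val at -3 and Ala at -1; everything else
#' is OTHER.
#'
#' @param sp_seq SP amino-acid string (length >= 3).
#' @param cleavage_pos 1-based index of the last SP residue (defaults to the
#'   sequence length).
#' @return List with `triplet` and `klass` (one of "AXA", "VXA", "OTHER").
#' @export
classify_c_motif <- function(sp_seq, cleavage_pos = nchar(sp_seq)) {
  if (nchar(sp_seq) < 3L || cleavage_pos < 3L) {
    stop("SP shorter than 3 residues has no (-3,-1) triplet", call. = FALSE)
  }
  triplet <- substr(sp_seq, cleavage_pos - 2L, cleavage_pos)
  m3 <- substr(triplet, 1L, 1L)
  m1 <- substr(triplet, 3L, 3L)
  klass <- if (m1 == "A" && m3 == "A") "AXA"
           else if (m1 == "A" && m3 == "V") "VXA"
           else "OTHER"
  list(triplet = triplet, klass = klass)
}

#' Classify translocation-pathway bias from per-residue hydrophobicity
#'
#' Uses the maximum window *mean* (per-residue scale): SPs at or below the
#' low threshold depend on the post-translational (Sec62/Sec63) route, SPs
#' at or above the high threshold are SRP-biased, the rest are intermediate.
#'
#' @param score_per_residue Numeric vector of max window means.
#' @param thresholds Length-2 numeric `c(low, high)`, default `c(1.75, 1.81)`.
#' @return Character vector over `{"post_dependent", "intermediate",
#'   "srp_biased"}`.
#' @export
classify_translocation_bias <- function(score_per_residue,
                                        thresholds = c(1.75, 1.81)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  ifelse(score_per_residue <= thresholds[1], "post_dependent",
         ifelse(score_per_residue >= thresholds[2], "srp_biased",
                "intermediate"))
}

#' Enumerate single-residue H-region deletions of an SP
#'
#' One variant per deletable H-region position; every variant is
#' re-decomposed with the hydropathy heuristic and re-scored. A variant is
#' flagged `exits_bad_band` when the original compound score lies inside the
#' configured band and the variant's does not.
#'
#' @param sp_seq SP amino-acid string (length >= 7).
#' @param decomp Decomposition list/row with `n_len`, `h_len`.
#' @param bad_band Length-2 numeric, inclusive score band (default
#'   `c(23, 24)`).
#' @param window Hydropathy window.
#' @return `data.frame` with one row per variant: `position`,
#'   `deleted_residue`, `variant_seq`, `h_len`, `max_window_mean`, `score`,
#'   `exits_bad_band`.
#' @export
enumerate_single_deletions <- function(sp_seq, decomp, bad_band = c(23, 24),
                                       window = 9L) {
  if (nchar(sp_seq) < 7L) stop("SP too short for deletion scan", call. = FALSE)
  in_band <- function(s) s >= bad_band[1] && s <= bad_band[2]
  orig <- compound_score(sp_seq, decomp$h_len, window)$score
  positions <- (decomp$n_len + 1L):(decomp$n_len + decomp$h_len)
  rows <- lapply(positions, function(p) {
    variant <- paste0(substr(sp_seq, 1L, p - 1L),
                      substr(sp_seq, p + 1L, nchar(sp_seq)))
    d <- decompose_regions(variant)
    cs <- compound_score(variant, d$h_len, window)
    data.frame(position = p,
               deleted_residue = substr(sp_seq, p, p),
               variant_seq = variant,
               h_len = d$h_len,
               max_window_mean = cs$max_window_mean,
               score = cs$score,
               exits_bad_band = in_band(orig) && !in_band(cs$score),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-SP feature table
#'
#' Computes the standard feature set for every SP of a cohort: region
#' lengths, N-region charge, max hydropathy window mean, compound score,
#' (-3,-1) motif class and translocation bias.
#'
#' @param sp_table SP table.
#' @param decomp Row-aligned decomposition table ([decompose_cohort()]);
#'   computed on the fly when `NULL`.
#' @param window Hydropathy window.
#' @param thresholds Translocation thresholds, see
#'   [classify_translocation_bias()].
#' @return `data.frame` with columns `gene_id`, `n_len`, `h_len`, `c_len`,
#'   `n_charge`, `n_positive`, `max_window_mean`, `compound_score`,
#'   `motif_class`, `triplet`, `translocation_bias`.
#' @export
sp_feature_table <- function(sp_table, decomp = NULL, window = 9L,
                             thresholds = c(1.75, 1.81)) {
  if (is.null(decomp)) decomp <- decompose_cohort(sp_table)
  stopifnot(nrow(sp_table) == nrow(decomp))
  n <- nrow(sp_table)
  out <- data.frame(gene_id = sp_table$gene_id,
                    n_len = decomp$n_len, h_len = decomp$h_len,
                    c_len = decomp$c_len,
                    n_charge = integer(n), n_positive = integer(n),
                    max_window_mean = numeric(n), compound_score = numeric(n),
                    motif_class = character(n), triplet = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- n_region_charge(sp_table$sp_seq[i], decomp$n_len[i])
    out$n_charge[i] <- ch$charge
    out$n_positive[i] <- ch$n_positive
    cs <- compound_score(sp_table$sp_seq[i], decomp$h_len[i], window)
    out$max_window_mean[i] <- cs$max_window_mean
    out$compound_score[i] <- cs$score
    mc <- classify_c_motif(sp_table$sp_seq[i], sp_table$cleavage_pos[i])
    out$motif_class[i] <- mc$klass
    out$triplet[i] <- mc$triplet
  }
  out$translocation_bias <- classify_translocation_bias(out$max_window_mean,
                                                        thresholds)
  out
}
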
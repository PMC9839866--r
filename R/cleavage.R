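SITE_POSITIONS <- c("-3", "-2", "-1", "+1", "+2")
SITE_OFFSETS <- c(`-3` = -2L, `-2` = -1L, `-1` = 0L, `+1` = 1L, `+2` = 2L)

#' Train a cleavage-site log-odds weight matrix
#'
#' A transparent position-specific scoring matrix over the five residue
#' slots -3..+2 around the cleavage bond (the bond follows the last SP
#' residue; there is no position 0). For each slot,
#' `weight = log2((count + pseudocount) / (n + 20 * pseudocount)) -
#' log2(background)`, where the background is the residue frequency over
#' all fused training sequences, smoothed with a pseudocount scaled to the
#' background's larger sample size so that a residue observed nowhere
#' scores exactly 0 instead of inheriting a spurious log-odds from the
#' smoothing asymmetry. This is a deliberately
#' simple stand-in for a learned cleavage predictor; its shifted-site counts
#' are soft, not exact, targets.
#'
#' @param sp_table SP table with cleavage positions (>= 20 rows).
#' @param mature_prefix Character vector (recycled) of mature-protein
#'   prefixes following each SP; at least 2 residues each. Defaults to the
#'   table's `mature_prefix` column.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Object of class `site_matrix`: list with `weights` (5 x 20
#'   matrix), `pseudocount`, `n_train`.
#' @export
train_site_matrix <- function(sp_table,
                              mature_prefix = sp_table$mature_prefix,
                              pseudocount = 1.0) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  n <- nrow(sp_table)
  if (n < 20L) stop("cohort too small to train a site matrix (need >= 20)",
                    call. = FALSE)
  if (is.null(mature_prefix)) stop("mature_prefix required", call. = FALSE)
  mature_prefix <- rep_len(toupper(mature_prefix), n)
  if (any(nchar(mature_prefix) < 2L)) {
    stop("mature context shorter than 2 residues", call. = FALSE)
  }
  fused <- paste0(sp_table$sp_seq, mature_prefix)
  cp <- sp_table$cleavage_pos
  counts <- matrix(0L, nrow = length(SITE_POSITIONS), ncol = length(AA20),
                   dimnames = list(SITE_POSITIONS, AA20))
  for (pos in SITE_POSITIONS) {
    idx <- cp + SITE_OFFSETS[[pos]]
    res <- substr(fused, idx, idx)
    res <- res[res %in% AA20]
    t0 <- table(factor(res, levels = AA20))
    counts[pos, ] <- as.integer(t0)
  }
  all_res <- unlist(strsplit(fused, "", fixed = TRUE))
  all_res <- all_res[all_res %in% AA20]
  bg_counts <- as.integer(table(factor(all_res, levels = AA20)))
  # background pseudocount scaled to the same effective rate as the
  # foreground's (pc per n slots), so fg and bg agree for unseen residues
  s <- pseudocount * length(all_res) / n
  bg <- (bg_counts + s) / (length(all_res) + 20 * s)
  weights <- counts  # dims/dimnames
  for (pos in SITE_POSITIONS) {
    fg <- (counts[pos, ] + pseudocount) / (sum(counts[pos, ]) + 20 * pseudocount)
    weights[pos, ] <- log2(fg) - log2(bg)
  }
  structure(list(weights = weights, pseudocount = pseudocount, n_train = n),
            class = "site_matrix")
}

# Sum of matrix weights for a candidate last-SP-residue position p in the
# fused sequence; residues outside the 20-letter alphabet contribute 0.
score_site <- function(fused, p, matrix) {
  w <- 0
  for (pos in SITE_POSITIONS) {
    i <- p + SITE_OFFSETS[[pos]]
    aa <- substr(fused, i, i)
    if (aa %in% AA20) w <- w + matrix$weights[pos, aa]
  }
  w
}

#' Re-predict the cleavage site of an SP fused to a new mature protein
#'
#' Scores every candidate last-SP-residue position within
#' `cleavage_pos +/- search_window` (clamped to `[4, len(fused) - 2]`) with
#' the site weight matrix and returns the argmax (leftmost on ties, which
#' keeps the native site when it ties a downstream competitor).
#'
#' @param sp_seq SP amino-acid string.
#' @param cleavage_pos Native cleavage position (last SP residue).
#' @param mature_prefix First residues of the grafted mature protein
#'   (>= 2).
#' @param matrix A `site_matrix` from [train_site_matrix()].
#' @param search_window Candidate range half-width (default 5).
#' @return List with `position`, `score`, `shifted` (position differs from
#'   the native one) and `new_triplet` (the (-3,-2,-1) residues at the
#'   predicted site).
#' @export
repredict_fusion <- function(sp_seq, cleavage_pos, mature_prefix, matrix,
                             search_window = 5L) {
  if (nchar(mature_prefix) < 2L) {
    stop("mature prefix shorter than 2 residues", call. = FALSE)
  }
  fused <- paste0(toupper(sp_seq), toupper(mature_prefix))
  lo <- max(4L, cleavage_pos - as.integer(search_window))
  hi <- min(nchar(fused) - 2L, cleavage_pos + as.integer(search_window))
  candidates <- lo:hi
  scores <- vapply(candidates, function(p) score_site(fused, p, matrix),
                   numeric(1L))
  best <- candidates[which.max(scores)]  # leftmost on ties
  list(position = best,
       score = max(scores),
       shifted = best != cleavage_pos,
       new_triplet = substr(fused, best - 2L, best))
}

#' Cleavage-shift report for a fused cohort
#'
#' Runs [repredict_fusion()] for every SP and tabulates the native vs new
#' (-3,-1) triplet (the "XYZ-ABC" notation pairs them across the hyphen),
#' the shift flag, and whether a shifted SP's new site recovered an AXA/VXA
#' motif.
#'
#' @param sp_table SP table.
#' @param mature_prefix Character vector (recycled) of mature prefixes;
#'   defaults to the table's `mature_prefix` column.
#' @param matrix A `site_matrix`.
#' @param search_window Candidate range half-width.
#' @return `data.frame` with columns `gene_id`, `original_triplet`,
#'   `new_position`, `new_triplet`, `motif_pair`, `shifted`,
#'   `recovered_motif`.
#' @export
shift_report <- function(sp_table, mature_prefix = sp_table$mature_prefix,
                         matrix, search_window = 5L) {
  n <- nrow(sp_table)
  mature_prefix <- rep_len(mature_prefix, n)
  out <- data.frame(gene_id = sp_table$gene_id,
                    original_triplet = character(n),
                    new_position = integer(n),
                    new_triplet = character(n),
                    motif_pair = character(n),
                    shifted = logical(n),
                    recovered_motif = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    orig <- classify_c_motif(sp_table$sp_seq[i], sp_table$cleavage_pos[i])
    pred <- repredict_fusion(sp_table$sp_seq[i], sp_table$cleavage_pos[i],
                             mature_prefix[i], matrix, search_window)
    m3 <- substr(pred$new_triplet, 1L, 1L)
    m1 <- substr(pred$new_triplet, 3L, 3L)
    out$original_triplet[i] <- orig$triplet
    out$new_position[i] <- pred$position
    out$new_triplet[i] <- pred$new_triplet
    out$motif_pair[i] <- paste0(orig$triplet, "-", pred$new_triplet)
    out$shifted[i] <- pred$shifted
    out$recovered_motif[i] <- pred$shifted && m1 == "A" && m3 %in% c("A", "V")
  }
  out
}

#' Serialise a site weight matrix to TSV
#'
#' @param matrix A `site_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(matrix, path) {
  tab <- data.frame(position = rownames(matrix$weights),
                    matrix$weights, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
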
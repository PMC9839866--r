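#' Decompose a signal peptide into N-, H- and C-regions
#'
#' Deterministic hydropathy heuristic used when a cohort table carries no
#' region boundaries. The H-region core is seeded at the contiguous window
#' of length `min(seed_window, len - 3)` with the highest mean
#' Kyte-Doolittle value (leftmost on ties), then extended left and right
#' while the adjacent residue has KD >= `extend_threshold`, and finally
#' clipped so that the N-region keeps at least 1 residue and the C-region at
#' least 2 (clipping from the H side nearer the violated bound). Everything
#' before the H-region is N, everything after is C.
#'
#' Sequences without a hydrophobic core (best window mean < 0) are returned
#' flagged, with the H-region fixed at the seed window, and a warning is
#' emitted.
#'
#' @param sp_seq SP amino-acid string, length >= 6.
#' @param seed_window Seed window length (default 7).
#' @param extend_threshold Minimum KD value for extending the core
#'   (default 1.0).
#' @return List with integer elements `n_len`, `h_len`, `c_len` and logical
#'   `flagged`.
#' @export
#' @examples
#' decompose_regions("MKRLLLLLLLLLSVSA")  # n=3, h=9, c=4
decompose_regions <- function(sp_seq, seed_window = 7L, extend_threshold = 1.0) {
  stopifnot(is.character(sp_seq), length(sp_seq) == 1L)
  n <- nchar(sp_seq)
  if (n < 6L) stop("SP sequence shorter than 6 residues", call. = FALSE)
  kdv <- kd_values(sp_seq, "sp_seq")
  w <- min(as.integer(seed_window), n - 3L)
  starts <- seq_len(n - w + 1L)
  means <- vapply(starts, function(i) mean(kdv[i:(i + w - 1L)], na.rm = TRUE),
                  numeric(1L))
  s <- which.max(means)            # leftmost maximum
  e <- s + w - 1L
  flagged <- FALSE
  if (means[s] < 0) {
    flagged <- TRUE
    warning("no hydrophobic core (all window means negative); decomposition flagged",
            call. = FALSE)
  } else {
    while (s > 1L && !is.na(kdv[s - 1L]) && kdv[s - 1L] >= extend_threshold) {
      s <- s - 1L
    }
    while (e < n && !is.na(kdv[e + 1L]) && kdv[e + 1L] >= extend_threshold) {
      e <- e + 1L
    }
  }
  if (s < 2L) s <- 2L            # keep n_len >= 1
  if (e > n - 2L) e <- n - 2L    # keep c_len >= 2
  list(n_len = s - 1L, h_len = e - s + 1L, c_len = n - e, flagged = flagged)
}

#' Decompose every SP of a cohort
#'
#' Table-provided boundaries (`n_end`, `h_end`) always override the
#' heuristic, so statistics on an annotated cohort use its annotations.
#'
#' @param sp_table SP table ([read_sp_table()] / [validate_sp_table()]).
#' @param seed_window,extend_threshold Passed to [decompose_regions()].
#' @return `data.frame` with columns `gene_id`, `n_len`, `h_len`, `c_len`,
#'   `flagged`, `provided` (TRUE when boundaries came from the table).
#' @export
decompose_cohort <- function(sp_table, seed_window = 7L, extend_threshold = 1.0) {
  stopifnot(nrow(sp_table) > 0L)
  n <- nrow(sp_table)
  out <- data.frame(gene_id = sp_table$gene_id,
                    n_len = integer(n), h_len = integer(n), c_len = integer(n),
                    flagged = logical(n), provided = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ne <- sp_table$n_end[i]; he <- sp_table$h_end[i]
    if (!is.na(ne) && !is.na(he)) {
      out$n_len[i] <- ne
      out$h_len[i] <- he - ne
      out$c_len[i] <- sp_table$cleavage_pos[i] - he
      out$provided[i] <- TRUE
    } else {
      d <- decompose_regions(sp_table$sp_seq[i], seed_window, extend_threshold)
      out$n_len[i] <- d$n_len
      out$h_len[i] <- d$h_len
      out$c_len[i] <- d$c_len
      out$flagged[i] <- d$flagged
    }
  }
  out
}

#' Check a region decomposition against its SP
#'
#' Returns violations rather than raising, so callers can collect them.
#'
#' @param sp One-row SP table (or list with `sp_seq`).
#' @param d Decomposition list/row with `n_len`, `h_len`, `c_len`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_decomposition <- function(sp, d) {
  len <- nchar(sp$sp_seq)
  v <- character(0)
  if (d$n_len + d$h_len + d$c_len != len) v <- c(v, "length mismatch")
  if (d$n_len < 1L) v <- c(v, "N-region too short")
  if (d$h_len < 1L) v <- c(v, "H-region too short")
  if (d$c_len < 2L) v <- c(v, "C-region too short")
  v
}
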
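#' Kyte-Doolittle hydropathy scale
#'
#' The published per-residue hydropathy values (Kyte & Doolittle 1982) used
#' throughout the package: window profiles, H-region detection and the
#' compound hydrophobicity score.
#'
#' @return Named numeric vector of length 20, one value per canonical
#'   amino-acid one-letter code.
#' @export
#' @examples
#' kyte_doolittle()[["L"]]  # 3.8
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Split a sequence into single residues; hard error on anything outside the
# 20 canonical letters plus 'X' (unknown residue, skipped downstream).
split_residues <- function(seq, context = "sequence") {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% c(AA20, "X")))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' in %s at position %d",
                 res[bad[1L]], context, bad[1L]), call. = FALSE)
  }
  res
}

# Per-residue KD values with NA for 'X' (excluded from statistics).
kd_values <- function(seq, context = "sequence") {
  res <- split_residues(seq, context)
  unname(kyte_doolittle()[res])
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Computes the arithmetic mean KD value of every contiguous window of
#' `window` residues (default 9, the setting used to locate the most
#' hydrophobic window of an SP). When the sequence is shorter than the
#' window, a single mean over the whole sequence is returned. 'X' residues
#' are excluded from the window means.
#'
#' @param seq Amino-acid string (canonical letters, 'X' allowed).
#' @param window Window size in residues.
#' @return List with elements `window` (the effective window used) and
#'   `means` (numeric vector, one value per window start position).
#' @export
#' @examples
#' kd_window_profile(strrep("L", 9))$means  # 3.8
kd_window_profile <- function(seq, window = 9L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  kdv <- kd_values(seq)
  n <- length(kdv)
  w <- min(as.integer(window), n)
  starts <- seq_len(n - w + 1L)
  means <- vapply(starts, function(i) mean(kdv[i:(i + w - 1L)], na.rm = TRUE),
                  numeric(1L))
  list(window = w, means = means)
}

#' Maximum hydrophobic window mean
#'
#' Convenience accessor: the maximum of [kd_window_profile()] means.
#'
#' @inheritParams kd_window_profile
#' @return Single numeric value.
#' @export
max_window_mean <- function(seq, window = 9L) {
  max(kd_window_profile(seq, window)$means)
}
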
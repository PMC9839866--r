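# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are written as naive loops, deliberately separate from
# the package's implementations.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(len, alphabet = AA_LETTERS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force maximum window mean over all windows of size w (shrunk to the
# sequence length when shorter), using the published KD scale directly.
brute_max_window_mean <- function(seq, w = 9L) {
  kd <- kyte_doolittle()
  res <- strsplit(seq, "")[[1]]
  vals <- kd[res]
  n <- length(vals)
  w <- min(w, n)
  best <- -Inf
  for (i in 1:(n - w + 1)) {
    s <- 0
    for (j in i:(i + w - 1)) s <- s + vals[[j]]
    if (s / w > best) best <- s / w
  }
  best
}

# Brute-force cleavage-site argmax: enumerate every candidate position and
# sum the matrix weights slot by slot.
brute_repredict <- function(sp_seq, cleavage_pos, mature, matrix, sw = 5L) {
  fused <- paste0(sp_seq, mature)
  offs <- c(-2L, -1L, 0L, 1L, 2L)
  slots <- c("-3", "-2", "-1", "+1", "+2")
  lo <- max(4L, cleavage_pos - sw)
  hi <- min(nchar(fused) - 2L, cleavage_pos + sw)
  best_p <- NA_integer_; best_s <- -Inf
  for (p in lo:hi) {
    s <- 0
    for (k in seq_along(offs)) {
      aa <- substr(fused, p + offs[k], p + offs[k])
      if (aa %in% colnames(matrix$weights)) {
        s <- s + matrix$weights[slots[k], aa]
      }
    }
    if (s > best_s + 1e-12) { best_s <- s; best_p <- p }
  }
  best_p
}

# Minimal valid SP table from bare sequences.
sp_table_from_seqs <- function(seqs, ...) {
  validate_sp_table(data.frame(gene_id = sprintf("G%03d", seq_along(seqs)),
                               sp_seq = seqs, ...,
                               stringsAsFactors = FALSE))
}

# A small cohort with AXA-style native sites and a shared mature context,
# enough rows to train a site matrix.
toy_axa_cohort <- function(n = 40L, mature = "DEDEDEDEDE") {
  seqs <- vapply(seq_len(n), function(i) {
    h <- paste(sample(c("L", "I", "V", "F"), 9, replace = TRUE), collapse = "")
    mid <- sample(c("S", "T", "Q", "G"), 1)
    paste0("MKR", h, "S", "A", mid, "A")
  }, character(1))
  tab <- sp_table_from_seqs(seqs)
  tab$mature_prefix <- mature
  tab
}
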
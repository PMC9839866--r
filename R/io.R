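# Strict line-based FASTA parser. Bulk readers silently drop letters they
# do not recognise; the io contract here is that nothing is dropped and
# invalid characters are reported with record and position, so records are
# assembled directly from the lines.
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(lines, ">")
  if (length(lines) == 0L || !is_header[1L]) {
    stop("not a FASTA file (no leading '>' header)", call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>\\s*", "", lines[is_header])
  grp <- factor(rec_idx[!is_header], levels = seq_along(headers))
  seqs <- vapply(split(lines[!is_header], grp),
                 paste, character(1L), collapse = "")
  seqs <- gsub("\\s", "", seqs)
  if (any(nchar(seqs) < 1L)) {
    stop("FASTA record with empty sequence", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("empty FASTA header id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  list(ids = unname(ids), headers = unname(headers),
       descriptions = unname(desc), seqs = unname(seqs))
}

#' Read a protein FASTA file
#'
#' Parses a protein FASTA into a data frame of sequence records. Residues are
#' uppercased; only the 20 canonical amino-acid letters are accepted, plus
#' 'X' which is allowed but flagged with a warning (such residues are
#' excluded from composition and hydropathy statistics downstream).
#'
#' @param path Path to a FASTA file.
#' @return `data.frame` with columns `id` (first header token), `description`
#'   (remainder of the header) and `residues`, in file order.
#' @export
read_protein_fasta <- function(path) {
  rec <- parse_fasta(path)
  ids <- rec$ids
  desc <- rec$descriptions
  seqs <- toupper(rec$seqs)
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!(res %in% c(AA20, "X")))
    if (length(bad) > 0L) {
      stop(sprintf("invalid residue '%s' in record '%s' at position %d",
                   res[bad[1L]], ids[i], bad[1L]), call. = FALSE)
    }
  }
  if (any(grepl("X", seqs, fixed = TRUE))) {
    warning("'X' residues present; they are excluded from composition and hydropathy statistics",
            call. = FALSE)
  }
  if (any(nchar(seqs) < 1L)) stop("empty sequence record", call. = FALSE)
  data.frame(id = unname(ids), description = unname(desc),
             residues = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a DNA (CDS) FASTA file
#'
#' Reads coding sequences; every record must have length divisible by 3.
#' A `chr=<label>` token in the header is parsed into the `chromosome`
#' column.
#'
#' @param path Path to a DNA FASTA file.
#' @return `data.frame` with columns `id`, `chromosome` (NA when absent) and
#'   `bases` (uppercase).
#' @export
read_cds_fasta <- function(path) {
  rec <- parse_fasta(path)
  ids <- rec$ids
  headers <- rec$headers
  chrom <- rep(NA_character_, length(ids))
  has_chr <- grepl("chr=", headers, fixed = TRUE)
  chrom[has_chr] <- sub("^.*chr=(\\S+).*$", "\\1", headers[has_chr])
  seqs <- toupper(rec$seqs)
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid base in record '%s' at position %d",
                 ids[i], bad[i]), call. = FALSE)
  }
  bad_len <- which(nchar(seqs) %% 3L != 0L)
  if (length(bad_len) > 0L) {
    stop(sprintf("CDS '%s' length %d not divisible by 3",
                 ids[bad_len[1L]], nchar(seqs[bad_len[1L]])), call. = FALSE)
  }
  data.frame(id = unname(ids), chromosome = unname(chrom),
             bases = unname(seqs), stringsAsFactors = FALSE)
}

SP_OPTIONAL_COLS <- c("cleavage_pos", "n_end", "h_end", "chromosome",
                      "location_label", "titer", "sp_cds")

#' Read a signal-peptide annotation table
#'
#' Reads a TSV with one annotated SP per row. Required columns: `gene_id`,
#' `sp_seq`. Optional: `cleavage_pos` (1-based index of the *last* SP
#' residue; defaults to `nchar(sp_seq)`), `n_end` / `h_end` (1-based indices
#' of the last N- and H-region residues), `chromosome`, `location_label`,
#' `titer` (U/L, non-negative), `sp_cds` (DNA, 3x the SP length). Any extra
#' columns (e.g. ground-truth `true_*` columns of synthetic cohorts) are
#' preserved.
#'
#' Invariants enforced per row, with the row number in the error message:
#' `nchar(sp_seq) == cleavage_pos`; when boundaries are present,
#' `1 <= n_end < h_end < cleavage_pos`; `titer >= 0`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return `data.frame` of SP annotations, rows in file order, all optional
#'   columns present (NA-filled when absent from the file).
#' @export
read_sp_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = c("NA", ""))
  for (col in c("gene_id", "sp_seq")) {
    if (!col %in% names(tab)) {
      stop(sprintf("required column '%s' missing from SP table", col),
           call. = FALSE)
    }
  }
  validate_sp_table(tab)
}

#' Validate (and normalise) an in-memory SP annotation table
#'
#' Applies the same defaults and invariant checks as [read_sp_table()] to a
#' data frame built in code.
#'
#' @param tab Data frame with at least `gene_id` and `sp_seq`.
#' @return The normalised table (all optional columns present).
#' @export
validate_sp_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("gene_id", "sp_seq") %in% names(tab)))
  tab$sp_seq <- toupper(as.character(tab$sp_seq))
  for (col in SP_OPTIONAL_COLS) {
    if (!col %in% names(tab)) {
      tab[[col]] <- if (col %in% c("cleavage_pos", "n_end", "h_end")) {
        NA_integer_
      } else if (col == "titer") NA_real_ else NA_character_
    }
  }
  tab$cleavage_pos <- ifelse(is.na(tab$cleavage_pos),
                             nchar(tab$sp_seq),
                             as.integer(tab$cleavage_pos))
  for (i in seq_len(nrow(tab))) {
    len <- nchar(tab$sp_seq[i])
    if (len < 1L) stop(sprintf("row %d: empty sp_seq", i), call. = FALSE)
    split_residues(tab$sp_seq[i], sprintf("row %d sp_seq", i))
    if (tab$cleavage_pos[i] != len) {
      stop(sprintf("row %d: cleavage_pos (%d) != sp_seq length (%d)",
                   i, tab$cleavage_pos[i], len), call. = FALSE)
    }
    ne <- tab$n_end[i]; he <- tab$h_end[i]
    if (xor(is.na(ne), is.na(he))) {
      stop(sprintf("row %d: n_end and h_end must be given together", i),
           call. = FALSE)
    }
    if (!is.na(ne)) {
      if (!(ne >= 1L && ne < he && he < tab$cleavage_pos[i])) {
        stop(sprintf(
          "row %d: region boundaries violate 1 <= n_end < h_end < cleavage_pos (n_end=%d, h_end=%d, cleavage_pos=%d)",
          i, ne, he, tab$cleavage_pos[i]), call. = FALSE)
      }
    }
    if (!is.na(tab$titer[i]) && tab$titer[i] < 0) {
      stop(sprintf("row %d: negative titer", i), call. = FALSE)
    }
    cds <- tab$sp_cds[i]
    if (!is.na(cds) && nchar(cds) != 3L * len) {
      stop(sprintf("row %d: sp_cds length %d != 3 x SP length %d",
                   i, nchar(cds), 3L * len), call. = FALSE)
    }
  }
  tab$n_end <- as.integer(tab$n_end)
  tab$h_end <- as.integer(tab$h_end)
  tab$titer <- as.numeric(tab$titer)
  rownames(tab) <- NULL
  tab
}

#' Write an SP annotation table to TSV
#'
#' Inverse of [read_sp_table()]; numeric columns are written at full
#' precision so that write-then-read round-trips exactly.
#'
#' @param tab SP table as returned by [read_sp_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sp_table <- function(tab, path) {
  out <- tab
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a set of named tables as TSV plus a JSON summary
#'
#' Each table is written as `<name>.tsv` (header row, '.' decimal, floats at
#' 6 significant digits) and a single `report.json` records the table names,
#' dimensions and output files. Output is deterministic: identical inputs
#' produce byte-identical files.
#'
#' @param tables Named list of data frames (may be empty).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written file paths (JSON last), invisibly.
#' @export
write_report <- function(tables, out_dir) {
  stopifnot(is.list(tables))
  if (length(tables) > 0L && is.null(names(tables))) {
    stop("tables must be named", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  paths <- character(0)
  summaries <- list()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    out <- tab
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), NA,
                             formatC(signif(out[[col]], 6L), format = "g",
                                     digits = 6L))
      }
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths <- c(paths, p)
    summaries[[nm]] <- list(rows = nrow(tab), cols = ncol(tab),
                            file = basename(p))
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(tables = summaries), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, json_path))
}
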
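#' Run the full SP analysis pipeline on a cohort
#'
#' Deduplicates the cohort, decomposes regions (table boundaries override
#' the heuristic), computes per-SP features, trains the cleavage-site
#' matrix and detects fusion-induced shifts (when mature context is
#' available), compares SP codon usage against a reference ORFeome (when
#' CDS are available), and assembles the cohort summaries and rule report.
#' When `out_dir` is given all tables are also written via
#' [write_report()].
#'
#' @param sp_table SP annotation table.
#' @param orfeome Optional reference CDS table ([read_cds_fasta()]) for
#'   codon-bias comparison.
#' @param genes_per_chromosome Optional named vector of gene totals per
#'   chromosome.
#' @param mature_prefix Mature-protein prefix(es) for fusion reprediction;
#'   defaults to the table's `mature_prefix` column when present.
#' @param out_dir Optional report directory.
#' @param bad_band,thresholds,rare_quantile,search_window,window Analysis
#'   settings with their standard defaults.
#' @return Named list of result tables: `dedup` (n_unique, n_removed),
#'   `decomp`, `features`, `composition`, `length_dist`, `shifts`,
#'   `codon_sp`, `codon_all`, `codon_delta`, `rare_share`, `chromosome`,
#'   `category_*`, `rules`, `logo`.
#' @export
run_sp_pipeline <- function(sp_table, orfeome = NULL,
                            genes_per_chromosome = NULL,
                            mature_prefix = NULL, out_dir = NULL,
                            bad_band = c(23, 24),
                            thresholds = c(1.75, 1.81),
                            rare_quantile = 0.25, search_window = 5L,
                            window = 9L) {
  dd <- dedupe(sp_table)
  cohort <- dd$cohort
  res <- list(dedup = data.frame(n_input = nrow(sp_table),
                                 n_unique = nrow(cohort),
                                 n_removed = dd$n_removed))

  decomp <- decompose_cohort(cohort)
  features <- sp_feature_table(cohort, decomp, window = window,
                               thresholds = thresholds)
  res$decomp <- decomp
  res$features <- features
  res$composition <- region_composition(cohort, decomp)
  ld <- length_distributions(cohort, decomp)
  res$length_dist <- ld
  res$frac_c5 <- ld$frac_c5

  # conservation logo over the modal SP length
  lens <- nchar(cohort$sp_seq)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  same <- cohort$sp_seq[lens == modal]
  if (length(same) >= 2L) {
    res$logo <- data.frame(position = seq_len(modal),
                           bits = positional_information(same))
  }

  if (is.null(mature_prefix) &&
      "mature_prefix" %in% names(cohort) &&
      !all(is.na(cohort$mature_prefix))) {
    mature_prefix <- cohort$mature_prefix
  }
  if (!is.null(mature_prefix)) {
    matrix <- train_site_matrix(cohort, mature_prefix)
    res$site_matrix <- matrix
    res$shifts <- shift_report(cohort, mature_prefix, matrix, search_window)
  }

  if (!is.null(orfeome) && "sp_cds" %in% names(cohort) &&
      !all(is.na(cohort$sp_cds))) {
    sp_cds <- cohort$sp_cds[!is.na(cohort$sp_cds)]
    res$codon_sp <- suppressWarnings(codon_fractions(sp_cds))
    res$codon_all <- suppressWarnings(codon_fractions(orfeome$bases))
    res$codon_delta <- compare_fractions(res$codon_sp, res$codon_all)
    res$rare_share <- rare_codon_share(sp_cds, res$codon_all, rare_quantile)
  }

  if (!is.null(genes_per_chromosome) && !all(is.na(cohort$chromosome))) {
    res$chromosome <- chromosome_distribution(cohort, genes_per_chromosome)
  }

  if (any(!is.na(cohort$titer))) {
    res$category_charge <- category_means(cohort, features$n_charge)
    res$category_score <- category_means(cohort,
                                         round_half_away(features$compound_score))
    res$category_motif <- category_means(cohort, features$motif_class)
    if (!is.null(res$shifts)) {
      res$category_shifted <- category_means(cohort, res$shifts$shifted)
    }
    if (!all(is.na(cohort$location_label))) {
      keep <- !is.na(cohort$location_label)
      res$category_location <- category_means(cohort[keep, , drop = FALSE],
                                              cohort$location_label[keep])
    }
  }

  shifted <- if (!is.null(res$shifts)) res$shifts$shifted
             else rep(FALSE, nrow(cohort))
  res$rules <- rule_report(features, shifted, bad_band)

  if (!is.null(out_dir)) {
    tables <- list(dedup = res$dedup, decomp = decomp, features = features,
                   composition = res$composition,
                   length_total = ld$total, length_n = ld$n,
                   length_h = ld$h, length_c = ld$c,
                   rules = res$rules)
    for (nm in c("logo", "shifts", "codon_delta", "chromosome",
                 "category_charge", "category_score", "category_motif",
                 "category_shifted", "category_location")) {
      if (!is.null(res[[nm]])) tables[[nm]] <- res[[nm]]
    }
    res$report_files <- write_report(tables, out_dir)
  }
  res
}
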
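# Synthetic SP cohort generator: the study conditions (region-length
# distributions, per-region composition, motif frequencies, shift rate,
# titer effect sizes) are encoded as defaults and every configured quantity
# is recoverable by the corresponding analysis stage.

default_chromosome_genes <- function() {
  c(I = 117L, II = 456L, III = 184L, IV = 900L, V = 323L, VI = 139L,
    VII = 611L, VIII = 321L, IX = 241L, X = 398L, XI = 348L, XII = 578L,
    XIII = 505L, XIV = 435L, XV = 597L, XVI = 560L)
}

# Relative (unnormalised) residue weights for the non-constrained part of
# each region's composition.
base_n_other <- function() {
  c(S = .13, T = .09, A = .09, L = .09, I = .06, V = .06, F = .05, G = .06,
    P = .05, N = .05, Q = .05, Y = .03, M = .04, W = .01, D = .025,
    E = .025, C = .01)
}
base_h_other <- function() {
  c(I = .13, V = .13, F = .10, A = .12, S = .06, T = .05, M = .03, W = .02,
    G = .04, C = .02, P = .02, Y = .03)
}
base_c_other <- function() {
  # polar and uncharged alphabet: no D/E/K/R/H/W in the C-region
  c(S = .18, T = .12, N = .08, Q = .07, G = .10, L = .05, V = .06, I = .03,
    F = .03, P = .045, Y = .02, M = .005, C = .005)
}

# Per-amino-acid baseline codon model: within each synonymous family
# (codons in alphabetical order) weights are proportional to k..1, giving a
# clear common/rare gradient.
default_codon_model <- function() {
  code <- sense_codons()
  fams <- split(names(code), unname(code))
  lapply(fams, function(codons) {
    codons <- sort(codons)
    k <- length(codons)
    stats::setNames(rev(seq_len(k)) / sum(seq_len(k)), codons)
  })
}

# Expected observed Ala share of the C-region as a function of the draw
# probability p of Ala, accounting for motif planting at -3/-1 and the
# degraded (-3,-1) of shifted SPs.
expected_ala_share <- function(p, len_c, p_axa, p_vxa, p_shifted, v_rel) {
  mean_c <- sum(len_c$values * len_c$probs)
  p_other_ns <- 1 - p_axa - p_vxa - p_shifted
  v <- v_rel * (1 - p)
  pa3 <- p_axa + p_other_ns * p
  pa1 <- (p_axa + p_vxa) + p_other_ns * p * (1 - p - v)
  (pa3 + pa1 + (mean_c - 2) * p) / mean_c
}

normalize_probs <- function(x) x / sum(x)

#' Construct synthetic-cohort parameters
#'
#' Bundles the full generative specification of a synthetic SP cohort. The
#' defaults encode the reference study conditions: region-length
#' distributions (N over 2-20 residues with mode 5 and a long tail, H over
#' 6-14 with mode 9, C over 3-8 with mode 5 carrying 64.38% of the mass),
#' per-region composition targets (N-region positive share 22.37% of which
#' 87.86% Arg+Lys, H-region Leu 26.59%, C-region Ala 23.26%), (-3,-1) motif
#' frequencies (AXA 0.199, VXA 0.211), a fusion-shift rate of 0.11 planted
#' only within OTHER-motif SPs, a rare-codon boost in SP coding regions, and
#' a feature-conditioned log-normal titer model (base 4106 U/L; multipliers
#' motif x1.3, N-charge +1 x1.2, shifted x0.51, bad-band x0.7).
#'
#' Composition *draw* distributions are derived from the observed-fraction
#' targets: the N-region positive block is scaled up to compensate for the
#' forced initiator Met, and the C-region Ala draw probability is solved so
#' the observed Ala share (including planted motif positions) matches the
#' target.
#'
#' @param n_sps Cohort size (rows, including duplicates).
#' @param n_duplicates Number of rows that duplicate an earlier SP sequence.
#' @param seed Integer seed for the cohort's pseudo-random stream.
#' @param strong_structure When TRUE, residues are drawn from strongly
#'   separated hydropathy alphabets (H from L/I/V/F, flanks from KD <= 0
#'   residues, no motif or shift planting); used for decomposition
#'   parameter-recovery cohorts.
#' @param ... Overrides for any parameter listed in the function body (e.g.
#'   `len_n = list(values = 3, probs = 1)`, `p_axa = 1`, `sigma = 0`).
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_sps = 352L, n_duplicates = 0L, seed = 1L,
                         strong_structure = FALSE, ...) {
  p <- list(
    n_sps = as.integer(n_sps),
    n_duplicates = as.integer(n_duplicates),
    seed = as.integer(seed),
    strong_structure = isTRUE(strong_structure),
    len_n = list(values = 2:20,
                 probs = normalize_probs(c(.05, .10, .16, .21, .16, .10, .07,
                                           .05, .03, .02, .012, .008, .006,
                                           .004, .003, .002, .002, .001,
                                           .001))),
    len_h = list(values = 6:14,
                 probs = normalize_probs(c(.03, .07, .16, .24, .18, .13,
                                           .09, .06, .04))),
    len_c = list(values = 3:8,
                 probs = c(.0362, .12, .6438, .10, .06, .04)),
    p_positive_n = 0.2237,
    p_rk_of_positive = 0.8786,
    p_leu_h = 0.2659,
    p_ala_c = 0.2326,
    p_axa = 0.199,
    p_vxa = 0.211,
    p_shifted = 0.11,
    mature_len = 10L,
    comp_mature = c(D = .35, E = .35, K = .15, W = .15),
    codon_model = default_codon_model(),
    rare_boost = 2.5,
    rare_quantile = 0.25,
    base_titer = 4106,
    sigma = 0.3,
    mult_motif = 1.3,
    mult_charge = 1.2,
    mult_shifted = 0.51,
    mult_bad_band = 0.7,
    bad_band = c(23, 24),
    calibrate_mean = TRUE,
    chromosome_genes = default_chromosome_genes(),
    chromosome_tilt = c(I = 2.1, XVI = 0.4),
    location_probs = c(secreted = .18, `cell wall` = .14,
                       `cell membrane` = .12, membrane = .22, ER = .10,
                       other = .24))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter '%s'", unknown[1L]), call. = FALSE)
  }
  p[names(dots)] <- dots

  stopifnot(p$p_axa >= 0, p$p_vxa >= 0, p$p_axa + p$p_vxa <= 1,
            p$p_shifted >= 0, p$base_titer > 0, p$sigma >= 0,
            p$n_duplicates >= 0L, p$n_duplicates < p$n_sps)
  if (p$p_shifted > 1 - p$p_axa - p$p_vxa + 1e-12) {
    stop("p_shifted cannot exceed the OTHER-motif probability (shifts are planted in OTHER-class SPs)",
         call. = FALSE)
  }
  for (ld in list(p$len_n, p$len_h, p$len_c)) {
    stopifnot(abs(sum(ld$probs) - 1) < 1e-9, all(ld$probs >= 0))
  }

  if (p$strong_structure) {
    p$comp_n <- normalize_probs(c(K = 2, R = 2, N = 1, Q = 1, S = 2, T = 2,
                                  D = 1, E = 1, G = 1))
    p$comp_h <- normalize_probs(c(L = 4, I = 2, V = 2, F = 1))
    p$comp_c <- normalize_probs(c(S = 3, T = 2, N = 1, Q = 1, G = 2))
    p$p_axa <- 0; p$p_vxa <- 0; p$p_shifted <- 0
  } else {
    # N-region: inflate the drawn positive share so the observed share
    # (with the forced Met at position 1) hits the target.
    mean_n <- sum(p$len_n$values * p$len_n$probs)
    scale <- if (mean_n > 1) mean_n / (mean_n - 1) else 1
    pos_draw <- min(p$p_positive_n * scale, 0.6)
    rk <- pos_draw * p$p_rk_of_positive
    comp_n <- c(K = rk * 0.53, R = rk * 0.47, H = pos_draw * (1 - p$p_rk_of_positive))
    other <- base_n_other()
    other <- other[setdiff(names(other), names(comp_n))]
    p$comp_n <- c(comp_n, other / sum(other) * (1 - pos_draw))

    comp_h_other <- base_h_other()
    p$comp_h <- c(L = p$p_leu_h,
                  comp_h_other / sum(comp_h_other) * (1 - p$p_leu_h))

    co <- base_c_other()
    v_rel <- co[["V"]] / sum(co)
    f <- function(x) expected_ala_share(x, p$len_c, p$p_axa, p$p_vxa,
                                        p$p_shifted, v_rel) - p$p_ala_c
    p_ala_draw <- if (f(1e-9) >= 0) 1e-9
                  else if (f(0.9) <= 0) 0.9
                  else stats::uniroot(f, c(1e-9, 0.9), tol = 1e-10)$root
    p$comp_c <- c(A = p_ala_draw, co / sum(co) * (1 - p_ala_draw))
  }
  for (nm in c("comp_n", "comp_h", "comp_c")) {
    stopifnot(abs(sum(p[[nm]]) - 1) < 1e-9)
  }

  # SP-region codon model: boost within-family rare codons and renormalise.
  rare <- lapply(p$codon_model, function(fam) {
    if (length(fam) < 2L) return(character(0))
    q <- stats::quantile(fam, p$rare_quantile, names = FALSE)
    names(fam)[fam < q]
  })
  p$codon_model_sp <- mapply(function(fam, rr) {
    w <- fam
    w[names(w) %in% rr] <- w[names(w) %in% rr] * p$rare_boost
    w / sum(w)
  }, p$codon_model, rare, SIMPLIFY = FALSE)

  cw <- as.numeric(p$chromosome_genes)
  names(cw) <- names(p$chromosome_genes)
  tilt <- p$chromosome_tilt
  cw[names(tilt)] <- cw[names(tilt)] * tilt
  p$chromosome_weights <- cw / sum(cw)

  class(p) <- "synth_params"
  p
}

draw_from <- function(probs, n = 1L) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

draw_length <- function(ld) {
  if (length(ld$values) == 1L) return(ld$values)
  sample(ld$values, 1L, prob = ld$probs)
}

# Back-translate an amino-acid residue vector with a per-family codon model.
back_translate <- function(residues, model) {
  paste(vapply(residues, function(aa) {
    fam <- model[[aa]]
    if (length(fam) == 1L) names(fam) else sample(names(fam), 1L, prob = fam)
  }, character(1L)), collapse = "")
}

#' Simulate one secretion titer from rule flags
#'
#' `titer = base_titer * prod(active multipliers) * noise`, where the noise
#' is mean-one log-normal (`exp(sigma * Z - sigma^2 / 2)`), so `sigma = 0`
#' returns the deterministic product and the expected titer equals the
#' multiplied base.
#'
#' @param true_flags Logical list/vector with elements `motif`,
#'   `charge_plus1`, `shifted`, `bad_band`.
#' @param params `synth_params` object.
#' @return Titer in U/L.
#' @export
simulate_titer <- function(true_flags, params) {
  mult <- titer_multiplier(true_flags, params)
  noise <- if (params$sigma == 0) 1
           else exp(stats::rnorm(1L, 0, params$sigma) - params$sigma^2 / 2)
  params$base_titer * mult * noise
}

titer_multiplier <- function(true_flags, params) {
  prod(c(if (isTRUE(true_flags$motif)) params$mult_motif,
         if (isTRUE(true_flags$charge_plus1)) params$mult_charge,
         if (isTRUE(true_flags$shifted)) params$mult_shifted,
         if (isTRUE(true_flags$bad_band)) params$mult_bad_band,
         1))
}

#' Sample one synthetic signal peptide
#'
#' Draws region lengths and residues, forces the initiator Met, plants the
#' (-3,-1) motif class per the configured frequencies, optionally (within
#' OTHER-class SPs) degrades the native site and plants a strong downstream
#' site in the mature prefix, back-translates the SP with the rare-boosted
#' codon model, and records all ground truth. Uses the current R RNG
#' stream; [simulate_cohort()] seeds it once from `params$seed`.
#'
#' @param params `synth_params` object.
#' @return One-row `data.frame` with sequence, annotation, `mature_prefix`
#'   and `true_*` ground-truth columns (no `gene_id`; the cohort assigns
#'   ids).
#' @export
sample_sp <- function(params) {
  n_len <- draw_length(params$len_n)
  h_len <- draw_length(params$len_h)
  c_len <- draw_length(params$len_c)
  n_res <- c("M", if (n_len > 1L) draw_from(params$comp_n, n_len - 1L))
  h_res <- draw_from(params$comp_h, h_len)
  c_res <- draw_from(params$comp_c, c_len)
  mature <- draw_from(params$comp_mature, params$mature_len)

  # (-3,-1) motif class, then conditional shift planting (OTHER class only,
  # so the marginal motif frequencies are preserved).
  u <- stats::runif(1L)
  shifted <- FALSE
  if (u < params$p_axa) {
    klass <- "AXA"
    c_res[c_len - 2L] <- "A"; c_res[c_len] <- "A"
  } else if (u < params$p_axa + params$p_vxa) {
    klass <- "VXA"
    c_res[c_len - 2L] <- "V"; c_res[c_len] <- "A"
  } else {
    klass <- "OTHER"
    p_other <- 1 - params$p_axa - params$p_vxa
    if (p_other > 0 && stats::runif(1L) < params$p_shifted / p_other) {
      shifted <- TRUE
      # weak native site: -3/-1 redrawn from the non-Ala C alphabet
      no_av <- params$comp_c[!names(params$comp_c) %in% c("A", "V")]
      no_av <- no_av / sum(no_av)
      c_res[c_len - 2L] <- draw_from(no_av)
      c_res[c_len] <- draw_from(no_av)
      # strong A-x-A site planted at +5, with a C-region-like -2 residue
      mature[3L] <- "A"; mature[4L] <- draw_from(params$comp_c)
      mature[5L] <- "A"
    } else if (c_res[c_len - 2L] %in% c("A", "V") && c_res[c_len] == "A") {
      no_a <- params$comp_c[names(params$comp_c) != "A"]
      c_res[c_len] <- draw_from(no_a / sum(no_a))
    }
  }

  sp_seq <- paste(c(n_res, h_res, c_res), collapse = "")
  sp_cds <- back_translate(c(n_res, h_res, c_res), params$codon_model_sp)
  len <- n_len + h_len + c_len

  charge <- n_region_charge(sp_seq, n_len)
  score <- max_window_mean(sp_seq) * h_len
  flags <- list(motif = klass %in% c("AXA", "VXA"),
                charge_plus1 = charge$charge == 1L,
                shifted = shifted,
                bad_band = score >= params$bad_band[1] &
                           score <= params$bad_band[2])

  data.frame(sp_seq = sp_seq,
             cleavage_pos = len,
             n_end = n_len,
             h_end = n_len + h_len,
             chromosome = draw_from(params$chromosome_weights),
             location_label = draw_from(params$location_probs),
             titer = simulate_titer(flags, params),
             sp_cds = sp_cds,
             mature_prefix = paste(mature, collapse = ""),
             true_n_len = n_len, true_h_len = h_len, true_c_len = c_len,
             true_motif_class = klass,
             true_shifted = shifted,
             true_charge = charge$charge,
             true_score = score,
             true_multiplier = titer_multiplier(flags, params),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic SP cohort in memory
#'
#' Generates `n_sps - n_duplicates` unique SPs (uniqueness of `sp_seq`
#' enforced by rejection sampling, 100 retries per slot), appends
#' `n_duplicates` rows that reuse an earlier SP sequence under a new gene
#' id (with a fresh titer draw), permutes row order, and optionally
#' rescales titers by the realized mean rule multiplier so the cohort mean
#' titer is centred on `base_titer` (`calibrate_mean`).
#'
#' The generator seeds R's RNG from `params$seed` and restores the caller's
#' RNG state on exit.
#'
#' @param params `synth_params` object.
#' @return Validated SP annotation table (see [read_sp_table()]) with
#'   ground-truth `true_*` columns.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)

  n_unique <- params$n_sps - params$n_duplicates
  rows <- vector("list", params$n_sps)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n_unique)) {
    for (try in seq_len(100L)) {
      row <- sample_sp(params)
      if (!exists(row$sp_seq, envir = seen)) break
      if (try == 100L) stop("could not sample a unique SP in 100 retries",
                            call. = FALSE)
    }
    assign(row$sp_seq, TRUE, envir = seen)
    rows[[i]] <- row
  }
  if (params$n_duplicates > 0L) {
    src <- sample(n_unique, params$n_duplicates, replace = TRUE)
    for (j in seq_len(params$n_duplicates)) {
      row <- rows[[src[j]]]
      flags <- list(motif = row$true_motif_class %in% c("AXA", "VXA"),
                    charge_plus1 = row$true_charge == 1L,
                    shifted = row$true_shifted,
                    bad_band = row$true_score >= params$bad_band[1] &
                               row$true_score <= params$bad_band[2])
      row$titer <- simulate_titer(flags, params)
      rows[[n_unique + j]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[sample(nrow(tab)), , drop = FALSE]
  tab <- cbind(gene_id = sprintf("SPG%04d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  if (isTRUE(params$calibrate_mean)) {
    tab$titer <- tab$titer / mean(tab$true_multiplier)
  }
  validate_sp_table(tab)
}

#' Simulate a synthetic ORFeome (CDS set)
#'
#' Coding sequences drawn from a flat amino-acid mix and the baseline codon
#' model; used as the reference set for codon-bias comparison and codon
#' fraction parameter-recovery.
#'
#' @param params `synth_params` object (for the codon model and seed).
#' @param n_orfs Number of ORFs.
#' @param len_codons Codons per ORF.
#' @param seed Seed (defaults to `params$seed + 1`).
#' @return `data.frame` with `id`, `chromosome`, `bases`.
#' @export
simulate_orfeome <- function(params, n_orfs = 400L, len_codons = 250L,
                             seed = params$seed + 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  aas <- names(params$codon_model)
  bases <- vapply(seq_len(n_orfs), function(i) {
    res <- c("M", sample(aas, len_codons - 1L, replace = TRUE))
    back_translate(res, params$codon_model)
  }, character(1L))
  data.frame(id = sprintf("ORF%05d", seq_len(n_orfs)),
             chromosome = sample(names(params$chromosome_weights), n_orfs,
                                 replace = TRUE,
                                 prob = params$chromosome_weights),
             bases = bases, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort on disk
#'
#' Writes the files the pipeline reads: `proteins.fasta` (SP + mature
#' prefix per gene), `cds.fasta` (SP coding sequences, `chr=` header
#' token), `orfeome.fasta` (reference CDS set) and `annotations.tsv` (the
#' SP table with ground-truth columns).
#'
#' @param params `synth_params` object.
#' @param out_dir Output directory (created if needed).
#' @param n_orfs,len_codons Passed to [simulate_orfeome()].
#' @return Named list of file paths; the in-memory tables are attached as
#'   attributes `sp_table` and `orfeome`.
#' @export
generate_cohort <- function(params, out_dir, n_orfs = 400L,
                            len_codons = 250L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  tab <- simulate_cohort(params)
  orfs <- simulate_orfeome(params, n_orfs, len_codons)

  protein_path <- file.path(out_dir, "proteins.fasta")
  writeLines(paste0(">", tab$gene_id, " synthetic precursor\n",
                    tab$sp_seq, tab$mature_prefix), protein_path)
  cds_path <- file.path(out_dir, "cds.fasta")
  writeLines(paste0(">", tab$gene_id, " chr=", tab$chromosome, "\n",
                    tab$sp_cds), cds_path)
  orf_path <- file.path(out_dir, "orfeome.fasta")
  writeLines(paste0(">", orfs$id, " chr=", orfs$chromosome, "\n",
                    orfs$bases), orf_path)
  tsv_path <- file.path(out_dir, "annotations.tsv")
  write_sp_table(tab, tsv_path)

  out <- list(proteins = protein_path, cds = cds_path, orfeome = orf_path,
              annotations = tsv_path)
  attr(out, "sp_table") <- tab
  attr(out, "orfeome") <- orfs
  out
}
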
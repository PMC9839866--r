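test_that("codon fractions normalise within synonymous families", {
  tab <- codon_fractions("TTATTG")
  leu <- tab[tab$aa == "L" & tab$count > 0, ]
  expect_equal(leu$codon, c("TTA", "TTG"))
  expect_equal(leu$fraction, c(0.5, 0.5))

  met <- codon_fractions("ATGATG")
  expect_equal(met$fraction[met$codon == "ATG"], 1.0)

  expect_error(codon_fractions(character(0)), "empty CDS")
  expect_error(codon_fractions("ATGA"), "divisible by 3")
  expect_warning(codon_fractions("ATGTAAATG"), "stop codon")
  expect_warning(codon_fractions("ATGANG"), "ambiguous")

  # family normalisation is exact on a large random set
  p <- synth_params(n_sps = 20, seed = 2)
  orfs <- simulate_orfeome(p, n_orfs = 40, len_codons = 100)
  big <- codon_fractions(orfs$bases)
  sums <- tapply(big$fraction, big$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fraction comparison is antisymmetric and conserves families", {
  p <- synth_params(n_sps = 20, seed = 2)
  orfs <- simulate_orfeome(p, n_orfs = 30, len_codons = 80)
  a <- codon_fractions(orfs$bases[1:15])
  b <- codon_fractions(orfs$bases[16:30])

  expect_equal(compare_fractions(a, a)$delta, rep(0, 61))
  ab <- compare_fractions(a, b)
  ba <- compare_fractions(b, a)
  expect_equal(ab$delta, -ba$delta)
  fam <- tapply(ab$delta, ab$aa, sum)
  expect_true(all(abs(fam) < 1e-9))
})

test_that("rare-codon share follows the within-family quantile rule", {
  # two-codon Lys family with reference fractions 0.9 / 0.1
  ref <- codon_fractions(paste(c(rep("AAA", 9), "AAG"), collapse = ""))
  expect_equal(rare_codon_share("AAGAAA", ref), 0.5)
  expect_equal(rare_codon_share("AAAAAA", ref), 0.0)
  expect_equal(rare_codon_share("AAGAAG", ref), 1.0)

  # balanced two-codon family: no strict minority, no rare codons
  ref2 <- codon_fractions("AAAAAG")
  expect_equal(rare_codon_share("AAGAAG", ref2), 0.0)
})

test_that("configured codon fractions are recovered from a synthetic ORFeome", {
  p <- synth_params(n_sps = 20, seed = 4)
  orfs <- simulate_orfeome(p, n_orfs = 400, len_codons = 250)  # 1e5 codons
  tab <- codon_fractions(orfs$bases)
  expected <- unlist(lapply(p$codon_model, function(fam) fam))
  names(expected) <- sub("^[^.]*\\.", "", names(expected))
  idx <- match(names(expected), tab$codon)
  got <- tab$fraction[idx]
  # per-codon multinomial band from the realized family totals
  fam_tot <- tapply(tab$count, tab$aa, sum)
  n_fam <- as.numeric(fam_tot[tab$aa[idx]])
  tol <- 4 * sqrt(expected * (1 - expected) / n_fam)
  expect_true(all(abs(got - expected) <= pmax(tol, 1e-12)))

  # SP coding regions are enriched for rare codons relative to the ORFeome
  cohort <- simulate_cohort(synth_params(n_sps = 400, seed = 4))
  share_sp <- rare_codon_share(cohort$sp_cds, tab)
  share_all <- rare_codon_share(orfs$bases, tab)
  expect_gt(share_sp, share_all)
})
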
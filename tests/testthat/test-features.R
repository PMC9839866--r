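test_that("KD window profile matches the published scale on uniform sequences", {
  expect_equal(kd_window_profile(strrep("L", 9))$means, 3.8)
  expect_equal(kd_window_profile(strrep("K", 9))$means, -3.9)
  # window shrinks to the sequence length
  prof <- kd_window_profile("LL")
  expect_equal(prof$window, 2L)
  expect_equal(prof$means, 3.8)
  expect_error(kd_window_profile("ML1"), "invalid residue")
})

test_that("max window mean equals brute-force enumeration", {
  set.seed(17)
  for (i in 1:200) {
    s <- random_aa_seq(sample(1:60, 1))
    for (w in c(3L, 9L)) {
      expect_equal(max_window_mean(s, w), brute_max_window_mean(s, w))
    }
  }
})

test_that("compound score multiplies the max window mean by H length", {
  cs <- compound_score("MKRLLLLLLLLLSVSA", 9L)
  expect_equal(cs$max_window_mean, 3.8)
  expect_equal(cs$score, 34.2)
  # sign follows the window mean
  expect_equal(compound_score(strrep("K", 12), 9L)$score, -35.1)
  # identity at unit H length and linearity in h_len
  expect_equal(compound_score("MKRLLLLLLLLLSVSA", 1L)$score, 3.8)
  expect_equal(compound_score("MKRLLLLLLLLLSVSA", 7L)$score, 7 * 3.8)
})

test_that("N-region charge counts K/R/H as positive and D/E as negative", {
  expect_equal(n_region_charge("MKRLLLL", 3L)$charge, 2L)
  expect_equal(n_region_charge("MDELLLL", 3L)$charge, -2L)
  ch <- n_region_charge("MKHLLLL", 3L)
  expect_equal(ch$charge, 2L)
  expect_equal(ch$n_positive, 2L)
})

test_that("region composition pools counts and normalises within region", {
  tab <- sp_table_from_seqs("MKLLLLLLSSA", n_end = 2L, h_end = 8L)
  comp <- region_composition(tab, decompose_cohort(tab))
  n_tab <- comp[comp$region == "N", ]
  expect_equal(n_tab$fraction[n_tab$aa == "M"], 0.5)
  expect_equal(n_tab$fraction[n_tab$aa == "K"], 0.5)

  tab2 <- sp_table_from_seqs(c("MKLLSSA", "MKVVSSA"),
                             n_end = 2L, h_end = 4L)
  comp2 <- region_composition(tab2, decompose_cohort(tab2))
  h_tab <- comp2[comp2$region == "H", ]
  expect_equal(h_tab$fraction[h_tab$aa == "L"], 0.5)
  expect_equal(h_tab$fraction[h_tab$aa == "V"], 0.5)

  for (r in c("N", "H", "C")) {
    expect_equal(sum(comp2$fraction[comp2$region == r]), 1, tolerance = 1e-9)
  }
  expect_error(region_composition(tab[0, ], decompose_cohort(tab)[0, ]),
               "empty cohort")
})

test_that("positional information spans [0, log2 20] with exact landmarks", {
  expect_equal(positional_information(c("A", "A", "A"))[1], log2(20))
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  expect_equal(positional_information(aa20)[1], 0)
  expect_equal(positional_information(c("A", "A", "L", "L"))[1], log2(20) - 1)

  # monotone decrease under added diversity at a position
  less <- positional_information(c("AA", "AA", "AA", "AA"))[1]
  more <- positional_information(c("AA", "AA", "LA", "VA"))[1]
  expect_lt(more, less)

  set.seed(9)
  seqs <- replicate(12, random_aa_seq(8))
  bits <- positional_information(seqs)
  expect_true(all(bits >= 0 - 1e-12 & bits <= log2(20) + 1e-12))

  expect_error(positional_information(c("AA", "AAA")), "same length")
  expect_error(positional_information("AA"), "at least 2")
})

test_that("(-3,-1) motif classification follows the AXA/VXA rule", {
  expect_equal(classify_c_motif("MKRLLLLLLLLLSALA")$klass, "AXA")
  expect_equal(classify_c_motif("MKRLLLLLLLLLSVSA")$klass, "VXA")
  expect_equal(classify_c_motif("MKRLLLLLLLLLSIAA")$klass, "OTHER")
  expect_equal(classify_c_motif("MKRLLLLLLLLLSALA")$triplet, "ALA")
  expect_error(classify_c_motif("MA"), "shorter than 3")

  # classes partition a cohort
  tab <- simulate_cohort(synth_params(n_sps = 120, seed = 8))
  feat <- sp_feature_table(tab)
  expect_equal(sum(feat$motif_class %in% c("AXA", "VXA", "OTHER")), 120L)
})

test_that("single-deletion scan re-scores variants and flags band exits", {
  sp <- "MKRLLLLASTLLSAVSA"   # compound score 23.1, inside [23, 24]
  d <- decompose_regions(sp)
  expect_equal(d$h_len, 9L)
  orig <- compound_score(sp, d$h_len)$score
  expect_true(orig >= 23 && orig <= 24)

  dels <- enumerate_single_deletions(sp, d)
  expect_equal(nrow(dels), d$h_len)
  for (i in seq_len(nrow(dels))) {
    dv <- decompose_regions(dels$variant_seq[i])
    cs <- compound_score(dels$variant_seq[i], dv$h_len)
    expect_equal(dels$score[i], cs$score)
    in_band <- cs$score >= 23 && cs$score <= 24
    expect_equal(dels$exits_bad_band[i], !in_band)
  }
  expect_true(any(dels$exits_bad_band))
})

test_that("translocation bias uses the per-residue thresholds", {
  expect_equal(classify_translocation_bias(1.70), "post_dependent")
  expect_equal(classify_translocation_bias(1.75), "post_dependent")
  expect_equal(classify_translocation_bias(1.78), "intermediate")
  expect_equal(classify_translocation_bias(1.81), "srp_biased")
  expect_equal(classify_translocation_bias(1.90), "srp_biased")
})
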
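test_that("site matrix training rewards dominant residues and centres uniform cohorts", {
  set.seed(31)
  tab <- toy_axa_cohort(60)
  m <- train_site_matrix(tab)
  expect_s3_class(m, "site_matrix")
  # -1 is always Ala in this cohort: its weight dominates the row
  expect_equal(names(which.max(m$weights["-1", ])), "A")

  # iid-uniform cohort: foreground ~ background, weights near 0
  seqs <- replicate(600, random_aa_seq(16))
  u <- sp_table_from_seqs(seqs)
  u$mature_prefix <- vapply(1:600, function(i) random_aa_seq(6), character(1))
  mu <- train_site_matrix(u)
  # 4-SD binomial band on a rate of 1/20, on the log2 scale (max over
  # 5 x 20 weight entries)
  tol <- log2(1 + 4 * sqrt(0.95 / (0.05 * 600)))
  expect_lt(max(abs(mu$weights)), tol)

  expect_error(train_site_matrix(tab, pseudocount = 0), "pseudocount")
  expect_error(train_site_matrix(tab[1:5, ]), "too small")
  expect_error(train_site_matrix(tab, mature_prefix = "D"), "shorter than 2")
})

test_that("fusion reprediction equals brute-force candidate enumeration", {
  set.seed(33)
  tab <- toy_axa_cohort(50)
  m <- train_site_matrix(tab)
  for (i in 1:50) {
    sp <- random_aa_seq(sample(14:22, 1))
    mature <- random_aa_seq(10)
    pred <- repredict_fusion(sp, nchar(sp), mature, m)
    expect_equal(pred$position,
                 brute_repredict(sp, nchar(sp), mature, m))
  }
})

test_that("a planted strong downstream site shifts the prediction", {
  set.seed(35)
  tab <- toy_axa_cohort(80)
  m <- train_site_matrix(tab)
  # weak native TST site; mature starts ASA -> candidate at +3 reads A-S-A
  sp <- "MKRLLLLLLLVTST"
  pred <- repredict_fusion(sp, nchar(sp), "ASADEDEDED", m)
  expect_true(pred$shifted)
  expect_equal(pred$position, nchar(sp) + 3L)
  expect_equal(pred$new_triplet, "ASA")

  # no competing site: native kept
  pred0 <- repredict_fusion("MKRLLLLLLLVSSA", 14L, "DEDEDEDEDE", m)
  expect_false(pred0$shifted)
})

test_that("ties keep the leftmost candidate, i.e. the native site", {
  tab <- toy_axa_cohort(40)
  m <- train_site_matrix(tab)
  m$weights[] <- 0
  m$weights["-1", "A"] <- 5
  # Ala at the native -1 and at +2 only: equal scores, native wins
  pred <- repredict_fusion("MKRLLLLLLLVSSA", 14L, "DADEDEDEDE", m)
  expect_false(pred$shifted)
  expect_equal(pred$position, 14L)

  expect_error(repredict_fusion("MKRLLLLLLLVSSA", 14L, "D", m),
               "shorter than 2")
})

test_that("shift report pairs native and new triplets and flags recovered motifs", {
  set.seed(37)
  tab <- toy_axa_cohort(40)
  m <- train_site_matrix(tab)
  rep <- shift_report(tab, matrix = m)
  expect_equal(nrow(rep), 40L)
  un <- !rep$shifted
  expect_true(all(rep$original_triplet[un] == rep$new_triplet[un]))
  expect_true(all(rep$motif_pair ==
                    paste0(rep$original_triplet, "-", rep$new_triplet)))
  expect_false(any(rep$recovered_motif[un]))
})

test_that("planted shift fraction is recovered within binomial error", {
  p <- synth_params(n_sps = 1500, seed = 13, p_shifted = 0.15)
  tab <- simulate_cohort(p)
  m <- train_site_matrix(tab)
  rep <- shift_report(tab, matrix = m)
  tol <- 3 * sqrt(0.15 * 0.85 / 1500)
  expect_lt(abs(mean(rep$shifted) - 0.15), tol)
  # shifted SPs mostly regain an AXA/VXA site at the new position
  expect_gt(mean(rep$recovered_motif[rep$shifted]), 0.8)
})
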
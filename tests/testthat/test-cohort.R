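test_that("dedupe keeps first occurrences and is idempotent", {
  tab <- sp_table_from_seqs(c("MKRLLLLLLLLLSVSA", "MKKLLLLLLLLLSVSA",
                              "MKRLLLLLLLLLSVSA", "MKRLLLLLLLLLSVSA"))
  dd <- dedupe(tab)
  expect_equal(nrow(dd$cohort), 2L)
  expect_equal(dd$n_removed, 2L)
  expect_equal(dd$cohort$gene_id[1], "G001")  # first occurrence kept
  dd2 <- dedupe(dd$cohort)
  expect_equal(dd2$n_removed, 0L)
  expect_equal(dd2$cohort, dd$cohort)
})

test_that("chromosome distribution divides SP counts by gene totals", {
  tab <- sp_table_from_seqs(rep("MKRLLLLLLLLLSVSA", 3),
                            chromosome = c("I", "I", "II"))
  gpc <- c(I = 20L, II = 30L, III = 10L)
  cd <- chromosome_distribution(tab, gpc)
  expect_equal(cd$pct[cd$chromosome == "I"], 10)
  expect_equal(cd$pct[cd$chromosome == "III"], 0)

  tab$chromosome[1] <- "XX"
  expect_error(chromosome_distribution(tab, gpc), "unknown chromosome")
  expect_error(chromosome_distribution(tab, c(I = 0L)), "zero genes")
})

test_that("length distributions report the five-residue C-region fraction", {
  tab <- sp_table_from_seqs(c("MKRLLLLLLLSTSSA", "MKKLLLLLLLSTSSA",
                              "MRRLLLLLLLSTSA"),
                            n_end = 3L, h_end = c(10L, 10L, 10L))
  ld <- length_distributions(tab, decompose_cohort(tab))
  expect_equal(ld$frac_c5, 2 / 3)
  expect_equal(sum(ld$total$count), 3L)
  expect_equal(sum(ld$c$fraction), 1)
})

test_that("category means summarise titers and partition the cohort", {
  tab <- sp_table_from_seqs(rep("MKRLLLLLLLLLSVSA", 5),
                            titer = c(2, 4, 10, NA, 6))
  cm <- category_means(tab, c("a", "a", "b", "b", "b"))
  expect_equal(cm$mean_titer[cm$category == "a"], 3)
  expect_equal(cm$sd_titer[cm$category == "a"], sqrt(2))
  expect_equal(cm$n[cm$category == "b"], 2L)  # NA titer excluded
  expect_equal(attr(cm, "n_no_titer"), 1L)
  expect_equal(sum(cm$n) + attr(cm, "n_no_titer"), nrow(tab))

  expect_warning(category_means(tab, c("a", "a", "a", "z", "a")),
                 "category 'z'")
  expect_error(category_means(sp_table_from_seqs("MKRLLLLLLLLLSVSA"), "a"),
               "no titers")
})

test_that("motif categories partition every titered SP", {
  tab <- simulate_cohort(synth_params(n_sps = 150, seed = 21))
  feat <- sp_feature_table(tab)
  cm <- category_means(tab, feat$motif_class)
  expect_equal(sum(cm$n), nrow(tab))
})

test_that("rule report scores the seven secretion rules and ranks deterministically", {
  # built to satisfy all seven rules: N=5 (charge +1), H=9, C=5, VSA motif
  best <- "MKAGALLLLLLLLLSSVSA"
  tab <- sp_table_from_seqs(c(best, "MKRLLLLASTLLSAVSA"),
                            n_end = c(5L, 3L), h_end = c(14L, 12L))
  feat <- sp_feature_table(tab, decompose_cohort(tab))
  rr <- rule_report(feat, shifted = c(FALSE, FALSE))
  expect_equal(rr$rule_count[rr$gene_id == "G001"], 7)
  # second SP has compound score 23.1: the score rule fails
  expect_false(rr$score_outside_band[rr$gene_id == "G002"])
  expect_equal(rr$rank, 1:2)
  rr2 <- rule_report(feat, shifted = c(FALSE, FALSE))
  expect_identical(rr, rr2)
})
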
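test_that("cohort generation is deterministic for a fixed seed", {
  p <- synth_params(n_sps = 40, seed = 12)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  c <- simulate_cohort(synth_params(n_sps = 40, seed = 13))
  expect_false(identical(a$sp_seq, c$sp_seq))
})

test_that("degenerate parameters yield fully constrained SPs", {
  p <- synth_params(n_sps = 30, seed = 6,
                    len_n = list(values = 3L, probs = 1),
                    len_h = list(values = 9L, probs = 1),
                    len_c = list(values = 5L, probs = 1),
                    p_axa = 1, p_vxa = 0, p_shifted = 0)
  tab <- simulate_cohort(p)
  expect_true(all(nchar(tab$sp_seq) == 17L))
  expect_true(all(substr(tab$sp_seq, 15, 15) == "A"))
  expect_true(all(substr(tab$sp_seq, 17, 17) == "A"))
  expect_true(all(substr(tab$sp_seq, 1, 1) == "M"))
  expect_true(all(tab$true_motif_class == "AXA"))
})

test_that("titer model honours flags exactly when noise is off", {
  p <- synth_params(n_sps = 20, seed = 1, sigma = 0)
  expect_equal(simulate_titer(list(), p), 4106)
  expect_equal(simulate_titer(list(shifted = TRUE), p), 0.51 * 4106)
  expect_equal(simulate_titer(list(motif = TRUE, charge_plus1 = TRUE), p),
               4106 * 1.3 * 1.2)
})

test_that("generated SPs satisfy the annotation invariants and are unique", {
  p <- synth_params(n_sps = 200, seed = 19)
  tab <- simulate_cohort(p)   # validate_sp_table runs inside
  expect_equal(nrow(tab), 200L)
  expect_true(all(tab$n_end >= 1 & tab$n_end < tab$h_end &
                    tab$h_end < tab$cleavage_pos))
  expect_true(all(nchar(tab$sp_cds) == 3 * nchar(tab$sp_seq)))
  expect_equal(dedupe(tab)$n_removed, 0L)
  # planted duplicates are found again by dedupe
  tabd <- simulate_cohort(synth_params(n_sps = 100, n_duplicates = 10,
                                       seed = 19))
  expect_equal(dedupe(tabd)$n_removed, 10L)
})

test_that("motif frequencies are recovered within binomial error", {
  p <- synth_params(n_sps = 2000, seed = 23)
  tab <- simulate_cohort(p)
  feat <- sp_feature_table(tab)
  expect_lt(abs(mean(feat$motif_class == "AXA") - 0.199),
            3 * sqrt(0.199 * 0.801 / 2000))
  expect_lt(abs(mean(feat$motif_class == "VXA") - 0.211),
            3 * sqrt(0.211 * 0.789 / 2000))
})

test_that("generated cohorts round-trip through files into the pipeline", {
  p <- synth_params(n_sps = 60, seed = 29)
  d <- withr::local_tempdir()
  files <- generate_cohort(p, d, n_orfs = 30, len_codons = 60)
  expect_true(all(file.exists(unlist(files))))

  tab <- read_sp_table(files$annotations)
  expect_equal(nrow(tab), 60L)
  orfs <- read_cds_fasta(files$orfeome)
  prot <- read_protein_fasta(files$proteins)
  expect_equal(nrow(prot), 60L)

  res <- run_sp_pipeline(tab, orfeome = orfs,
                         genes_per_chromosome = p$chromosome_genes,
                         out_dir = file.path(d, "report"))
  expect_equal(res$dedup$n_unique, 60L)
  expect_true(file.exists(file.path(d, "report", "report.json")))

  # byte-identical regeneration under the same seed
  d2 <- withr::local_tempdir()
  files2 <- generate_cohort(p, d2, n_orfs = 30, len_codons = 60)
  expect_identical(readLines(files$annotations), readLines(files2$annotations))
  expect_identical(readLines(files$cds), readLines(files2$cds))
})
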
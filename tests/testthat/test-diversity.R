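test_that("allele frequencies count gene copies over typed individuals", {
  panel <- marker_panel("S1", "SNP", category = "cat3")
  gt <- genotype_table(tibble::tibble(id = c("a", "b"),
                                      S1_1 = c("A", "A"), S1_2 = c("A", "T")),
                       panel)
  fr <- allele_frequencies(gt)
  expect_equal(fr$freq[fr$allele == "A"], 0.75)
  expect_equal(fr$freq[fr$allele == "T"], 0.25)
  expect_equal(fr$n_typed, c(2L, 2L))

  gt2 <- genotype_table(tibble::tibble(id = c("a", "b"),
                                       S1_1 = c(NA, NA), S1_2 = c(NA, NA)),
                        panel)
  expect_error(allele_frequencies(gt2), "S1")
})

test_that("frequencies match a brute-force tally on random tables", {
  for (seed in 1:3) {
    gt <- random_table(12, 4, n_alleles = 5, seed = seed, missing_rate = 0.15)
    fr <- allele_frequencies(gt)
    for (l in gt_panel(gt)$locus) {
      o <- oracle_locus_stats(gt, l)
      fl <- fr[fr$locus == l, ]
      expect_equal(setNames(fl$freq, fl$allele),
                   setNames(unname(o$p), names(o$p)))
      expect_equal(sum(fl$freq), 1, tolerance = 1e-12)
    }
  }
})

test_that("locus statistics reproduce closed forms at a balanced biallelic locus", {
  # 50 individuals, allele counts exactly 50/50
  panel <- marker_panel("S1", "SNP", category = "cat3")
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:50),
    S1_1 = c(rep("A", 10), rep("C", 10), rep("A", 30)),
    S1_2 = c(rep("A", 10), rep("C", 10), rep("C", 30))), panel)
  st <- locus_stats(gt, hw_reps = 1000, seed = 1)
  expect_equal(st$he, 0.5)
  expect_equal(st$ne, 2)
  expect_equal(st$pic, 0.375)
  expect_equal(st$pid_u, 0.375)
  expect_equal(st$pid_sib, 0.59375)
  expect_equal(st$maf, 0.5)
  # no rarefaction (g = gene count) keeps the observed allele count
  st_full <- locus_stats(gt, g = 100, hw_reps = 1000, seed = 1)
  expect_equal(st_full$nar, 2)
})

test_that("null-allele frequency uses the heterozygote-deficit ratio", {
  # He = 0.76, Ho = 0.32 as printed for a strongly null-affected locus
  expect_equal(round(vinekin:::fnull_chakraborty(0.76, 0.32), 4), 0.4074)
  expect_lt(abs(vinekin:::fnull_chakraborty(0.76, 0.32) - 0.4073), 2e-4)
  expect_equal(vinekin:::fnull_brookfield(0.5, 0.5), 0)
})

test_that("all per-locus statistics equal the enumeration oracle", {
  for (seed in 4:8) {
    gt <- random_table(10, 5, n_alleles = 4, seed = seed, missing_rate = 0.1)
    st <- locus_stats(gt, hw_reps = 1000, seed = 1)
    for (i in seq_len(nrow(st))) {
      o <- oracle_locus_stats(gt, st$locus[i])
      expect_equal(st$he[i], o$he, tolerance = 1e-12)
      expect_equal(st$ho[i], o$ho, tolerance = 1e-12)
      expect_equal(st$ne[i], o$ne, tolerance = 1e-12)
      expect_equal(st$na[i], o$na)
      expect_equal(st$pic[i], o$pic, tolerance = 1e-12)
      expect_equal(st$pid_u[i], o$pid_u, tolerance = 1e-12)
      expect_equal(st$pid_sib[i], o$pid_sib, tolerance = 1e-12)
    }
  }
})

test_that("statistics satisfy their structural inequalities", {
  gt <- random_table(30, 8, n_alleles = 6, seed = 99, missing_rate = 0.05)
  st <- locus_stats(gt, hw_reps = 1000, seed = 2)
  expect_true(all(st$pid_sib >= st$pid_u))
  expect_true(all(st$pic <= st$he + 1e-12))
  expect_equal(st$ne, 1 / (1 - st$he), tolerance = 1e-12)
  expect_true(all(st$nar <= st$na + 1e-9))
  expect_true(all(st$f >= -1 & st$f <= 1, na.rm = TRUE))
})

test_that("rarefied richness at two gene copies equals 1 + unbiased gene diversity", {
  gt <- random_table(20, 3, n_alleles = 5, seed = 55)
  st <- locus_stats(gt, g = 2, hw_reps = 1000, seed = 1)
  fr <- allele_frequencies(gt)
  for (i in seq_len(nrow(st))) {
    fl <- fr[fr$locus == st$locus[i], ]
    G <- 2 * fl$n_typed[1]
    he_unb <- 1 - sum(fl$count * (fl$count - 1)) / (G * (G - 1))
    expect_equal(st$nar[i], 1 + he_unb, tolerance = 1e-12)
  }
})

test_that("monomorphic loci use the degenerate conventions", {
  panel <- toy_ssr_panel("L1")
  gt <- toy_table(list(id = c("a", "b"), L1_1 = c(100, 100), L1_2 = c(100, 100)),
                  panel)
  st <- locus_stats(gt, hw_reps = 1000)
  expect_equal(st$he, 0); expect_equal(st$ne, 1); expect_equal(st$pic, 0)
  expect_equal(st$pid_u, 1); expect_equal(st$pid_sib, 1)
  expect_true(is.na(st$f)); expect_true(is.na(st$fnull))
  expect_equal(st$hw, "ND")
})

test_that("Hardy-Weinberg tests detect gross departures and accept HW tables", {
  panel <- toy_ssr_panel("L1")
  # exact HW proportions, p = q = 0.5: 25 AA, 50 AB, 25 BB
  gt_hw <- toy_table(list(id = sprintf("i%03d", 1:100),
                          L1_1 = c(rep(100, 25), rep(100, 50), rep(102, 25)),
                          L1_2 = c(rep(100, 25), rep(102, 50), rep(102, 25))),
                     panel)
  p_hw <- hw_exact_test(gt_hw, "L1")
  expect_gt(p_hw$p, 0.5)
  expect_equal(p_hw$verdict, "NS")
  # complete homozygote excess at a two-allele locus
  gt_hom <- toy_table(list(id = sprintf("i%02d", 1:50),
                           L1_1 = c(rep(100, 25), rep(102, 25)),
                           L1_2 = c(rep(100, 25), rep(102, 25))), panel)
  p_hom <- hw_exact_test(gt_hom, "L1")
  expect_lt(p_hom$p, 0.001)
  expect_equal(p_hom$verdict, "***")
  # multiallelic Monte Carlo path agrees with the biallelic verdicts in kind
  gt3 <- toy_table(list(id = sprintf("i%02d", 1:60),
                        L1_1 = rep(c(100, 102, 104), 20),
                        L1_2 = rep(c(100, 102, 104), 20)), panel)
  p3 <- hw_exact_test(gt3, "L1", reps = 2000, seed = 4)
  expect_lt(p3$p, 0.001)
  expect_error(hw_exact_test(gt3, "L1", reps = 10), "1000")
})

test_that("cumulative identity probabilities multiply across loci", {
  gt <- random_table(15, 4, n_alleles = 4, seed = 31)
  st <- locus_stats(gt, hw_reps = 1000, seed = 1)
  one <- cumulative_pid(st, loci = st$locus[1])
  expect_equal(one$cum_pid_u, st$pid_u[1])
  all4 <- cumulative_pid(st)
  expect_equal(all4$cum_pid_u, prod(st$pid_u))
  expect_equal(all4$cum_pid_sib, prod(st$pid_sib))
  expect_error(cumulative_pid(st, loci = "missing"), "not in stats")
})

test_that("panel equivalence finds the smallest sufficient locus prefix", {
  gt <- random_table(20, 6, n_alleles = 5, seed = 41)
  st <- locus_stats(gt, hw_reps = 1000, seed = 1)
  expect_equal(as.integer(panel_equivalence(st, prod(st$pid_sib))), 6L)
  expect_equal(as.integer(panel_equivalence(st, min(st$pid_sib))), 1L)
  expect_error(panel_equivalence(st, prod(st$pid_sib) / 10), "insufficient")
})

test_that("panel summaries are unweighted means plus total allele count", {
  gt <- random_table(20, 5, n_alleles = 5, seed = 43)
  st <- locus_stats(gt, hw_reps = 1000, seed = 1)
  ps <- panel_summary(st)
  expect_equal(ps$total_a, sum(st$na))
  expect_equal(ps$mean_pic, mean(st$pic))
  one <- panel_summary(st[1, ])
  expect_equal(one$mean_ho, st$ho[1])
  expect_equal(one$total_a, st$na[1])
})
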
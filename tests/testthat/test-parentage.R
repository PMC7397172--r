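test_that("single-locus likelihood ratios follow the Mendelian closed forms", {
  p <- c(A = 0.25, B = 0.5, C = 0.25)
  # error-free: offspring AB with homozygous AA parent -> ratio 1/(2 pA)
  r <- transition_probability(c("A", "B"), c("A", "A"), freqs = p, eps = 0)
  expect_equal(r, 1 / (2 * 0.25))
  # heterozygous parent AB, offspring AA -> T = 0.5 * pA; P(go) = pA^2
  r2 <- transition_probability(c("A", "A"), c("A", "B"), freqs = p, eps = 0)
  expect_equal(r2, (0.5 * 0.25) / 0.25^2)
  # incompatible candidate excludes at eps = 0, stays finite at eps > 0
  r0 <- transition_probability(c("A", "A"), c("B", "C"), freqs = p, eps = 0)
  expect_equal(r0, 0)
  r_eps <- transition_probability(c("A", "A"), c("B", "C"), freqs = p, eps = 0.01)
  expect_gt(r_eps, 0)
  expect_lt(log(r_eps), 0)
  # trio ratio: parents AA x BB must produce AB
  rt <- transition_probability(c("A", "B"), c("A", "A"), c("B", "B"),
                               freqs = p, eps = 0)
  expect_equal(rt, 1 / (2 * 0.25 * 0.5))
  expect_error(transition_probability(c("A", "B"), c("A", "A"), freqs = p,
                                      eps = 0.7), "eps")
})

test_that("alleles absent from the frequency table get a floor with a warning", {
  p <- structure(c(A = 0.5, B = 0.5), gene_count = 100)
  expect_warning(r <- transition_probability(c("A", "Z"), c("Z", "Z"),
                                             freqs = p, eps = 0),
                 "floor")
  expect_true(is.finite(r) && r > 0)
})

test_that("multilocus LOD is the sum of per-locus log ratios", {
  panel <- toy_ssr_panel(c("L1", "L2"))
  gt <- toy_table(list(id = c("o", "p", "q"),
                       L1_1 = c(100, 100, 104), L1_2 = c(102, 100, 106),
                       L2_1 = c(200, 200, 200), L2_2 = c(202, 202, 204)), panel)
  fr <- allele_frequencies(gt)
  res <- lod_parentage(gt, "o", "p", eps = 0.01, freqs = fr)
  manual <- log(transition_probability(c(100, 102), c(100, 100),
                                       freqs = vinekin:::freq_vector(fr, "L1"),
                                       eps = 0.01)) +
            log(transition_probability(c(200, 202), c(200, 202),
                                       freqs = vinekin:::freq_vector(fr, "L2"),
                                       eps = 0.01))
  expect_equal(res$lod, manual)
  expect_equal(res$loci_compared, 2L)
  expect_equal(res$mismatches, 0L)
  # q shares nothing with o at L1
  res_q <- lod_parentage(gt, "o", "q", eps = 0.01, freqs = fr)
  expect_equal(res_q$mismatches, 1L)
})

test_that("a lone always-true candidate is always assigned correctly", {
  founders <- random_table(12, 10, n_alleles = 6, seed = 201)
  suppressWarnings({
    sim <- simulate_critical_lod(
      founders[1, ], loci = gt_panel(founders)$locus,
      cfg = parentage_sim_config(n_offspring = 300, prop_sampled = 1,
                                 error_rate = 0, typed_rate = 1),
      seed = 5, freqs = allele_frequencies(founders))
  })
  expect_true(all(sim$reliability == 1))
  expect_true(all(sim$critical_lod[sim$analysis == "duo"] <=
                    max(0, min(attr(sim, "duo_lod"), na.rm = TRUE)) + 1e-9))
  expect_true(all(sim$critical_lod[sim$analysis == "trio"] <=
                    max(0, min(attr(sim, "trio_lod"), na.rm = TRUE)) + 1e-9))
})

test_that("critical LOD thresholds are stable across simulation seeds", {
  founders <- parentage_founders(seed = 202, n = 127, n_ssr = 20)$table
  crit <- vapply(c(31, 32, 33), function(s) {
    sl <- simulate_critical_lod(
      founders, cfg = parentage_sim_config(n_offspring = 10000,
                                           error_rate = 0.01,
                                           prop_sampled = 0.85),
      seed = s)
    sl$critical_lod[sl$analysis == "trio" & sl$level == "strict95"]
  }, 1)
  expect_lt(diff(range(crit)), 0.5)
})

test_that("raising the error rate lowers true-parent LODs", {
  founders <- parentage_founders(seed = 203, n = 40, n_ssr = 12)$table
  mean_lod <- vapply(c(0, 0.05, 0.15), function(e) {
    sl <- simulate_critical_lod(
      founders, cfg = parentage_sim_config(n_offspring = 1500, error_rate = e,
                                           prop_sampled = 1),
      seed = 6)
    mean(attr(sl, "trio_lod")[attr(sl, "trio_correct")], na.rm = TRUE)
  }, 1)
  expect_true(all(diff(mean_lod) < 0))
})

test_that("the mismatch budget rejects two-locus conflicts in a 20-locus trio", {
  fd <- parentage_founders(seed = 204, n = 30, n_ssr = 20)
  founders <- fd$table
  ped <- gen_pedigree(founders, n_trios = 1, error_rate = 0, seed = 7)
  tab <- tibble::as_tibble(ped$table)
  off <- ped$truth$offspring[1]
  # corrupt two loci with alleles carried by neither parent
  for (l in c("ssr01", "ssr02")) {
    big <- max(tab[[paste0(l, "_2")]], na.rm = TRUE) + 40L
    tab[tab$id == off, paste0(l, "_1")] <- big
    tab[tab$id == off, paste0(l, "_2")] <- big
  }
  gt <- genotype_table(tab, gt_panel(ped$table))
  res <- assign_parentage(gt, off, founders$id, critical = -100, eps = 0.01,
                          freqs = suppressWarnings(allele_frequencies(gt)))
  expect_false(res$type[1] == "trio" &&
                 res$mismatches[1] <= floor(0.05 * res$loci_compared[1]))
})

test_that("offspring typed at too few loci are skipped with a warning", {
  founders <- parentage_founders(seed = 205, n = 20, n_ssr = 12)$table
  tab <- tibble::as_tibble(founders)
  tab[1, paste0("ssr", sprintf("%02d", 4:12), "_1")] <- NA_integer_
  tab[1, paste0("ssr", sprintf("%02d", 4:12), "_2")] <- NA_integer_
  gt <- genotype_table(tab, gt_panel(founders))
  expect_warning(res <- assign_parentage(gt, gt$id[1], gt$id[-1],
                                         critical = 5, eps = 0.01),
                 "Skipping")
  expect_equal(nrow(res), 0)
})

test_that("loci with high null-allele estimates are excluded from parentage", {
  sim <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 80, n_ssr = 10,
                                       n_snp = 0, n_cp = 0, seed = 206,
                                       null_locus = TRUE, null_freq = 0.3,
                                       high_missing_locus = FALSE,
                                       missing_rate = 0))
  st <- locus_stats(sim$table, hw_reps = 1000, seed = 1)
  keep <- suppressMessages(parentage_panel(st))
  expect_false(sim$truth$null_locus$locus %in% keep)
  expect_gt(st$fnull[st$locus == sim$truth$null_locus$locus], 0.1)
})

test_that("first-degree screening keeps relatives and discards the unrelated", {
  # unrelated pairs at 20 loci x 10 equifrequent alleles pass rarely
  gt <- random_table(40, 20, n_alleles = 10, seed = 207)
  hk <- halfkin_screen(gt, eps = 0.01)
  expect_lt(nrow(hk) / choose(40, 2), 0.01)
  # true parent-offspring pairs always share an allele everywhere (eps = 0)
  fd <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 25, n_ssr = 20,
                                      n_snp = 0, n_cp = 0, seed = 208,
                                      high_missing_locus = FALSE,
                                      missing_rate = 0))
  ped <- gen_pedigree(fd$table, n_trios = 8, error_rate = 0, seed = 209)
  hk2 <- halfkin_screen(ped$table, eps = 0.01)
  pair_in <- function(a, b) {
    any((hk2$id_a == a & hk2$id_b == b) | (hk2$id_a == b & hk2$id_b == a))
  }
  expect_true(all(mapply(pair_in, ped$truth$offspring, ped$truth$mother)))
  expect_true(all(mapply(pair_in, ped$truth$offspring, ped$truth$father)))
  # a pair failing at two of twenty loci is excluded
  tab <- tibble::as_tibble(fd$table)[1:2, ]
  for (l in c("ssr01", "ssr02")) {
    tab[2, paste0(l, "_1")] <- max(tab[[paste0(l, "_2")]], na.rm = TRUE) + 40L
    tab[2, paste0(l, "_2")] <- tab[[2, paste0(l, "_1")]]
  }
  for (l in sprintf("ssr%02d", 3:20)) {  # make the rest identical
    tab[2, paste0(l, "_1")] <- tab[1, paste0(l, "_1")]
    tab[2, paste0(l, "_2")] <- tab[1, paste0(l, "_2")]
  }
  gt2 <- genotype_table(tab, gt_panel(fd$table))
  hk3 <- halfkin_screen(gt2, eps = 0.01,
                        freqs = suppressWarnings(allele_frequencies(gt2)))
  expect_equal(nrow(hk3), 0)
})
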
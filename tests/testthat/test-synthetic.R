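test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_pop_config(n_pools = 2, pool_sizes = c(15, 15), n_ssr = 10,
                        n_snp = 5, n_cp = 4, seed = 401)
  a <- gen_population(cfg); b <- gen_population(cfg)
  expect_equal(tibble::as_tibble(a$table), tibble::as_tibble(b$table))
  expect_equal(a$truth$ancestry, b$truth$ancestry)
  expect_error(sim_pop_config(n_pools = 1), "seed")
})

test_that("a single panmictic pool is in Hardy-Weinberg proportions", {
  sim <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 120,
                                       n_ssr = 25, n_snp = 0, n_cp = 0,
                                       seed = 402, high_missing_locus = FALSE,
                                       missing_rate = 0))
  st <- locus_stats(sim$table, hw_reps = 1000, seed = 1)
  # Ho is binomial around He: check each locus within 3 binomial sd
  z <- abs(st$ho - st$he) / sqrt(pmax(st$he * (1 - st$he), 1e-9) / st$n)
  expect_lt(mean(z > 3), 0.1)
  expect_lt(abs(mean(st$ho) - mean(st$he)), 0.05)
})

test_that("pool divergence vanishes as drift goes to zero", {
  sim <- gen_population(sim_pop_config(n_pools = 2, pool_sizes = c(25, 25),
                                       drift = 0.001, n_ssr = 15, n_snp = 0,
                                       n_cp = 0, seed = 403,
                                       high_missing_locus = FALSE,
                                       missing_rate = 0))
  dm <- psa_distance(sim$table)
  g <- setNames(paste0("p", sim$truth$ancestry$pool), sim$table$id)
  am <- amova(dm, g, n_perm = 199, seed = 404)
  expect_lt(am$phi_pt, 0.05)
})

test_that("generated panels match their configured marginals", {
  sim <- gen_population(sim_pop_config(seed = 405))
  panel <- gt_panel(sim$table)
  expect_equal(nrow(sim$table), 127)
  expect_equal(sum(panel$system == "SSR"), 36)
  expect_equal(sum(panel$system == "SNP"), 45)
  st <- locus_stats(sim$table, loci = panel_loci(panel, system = "SSR"),
                    hw_reps = 1000, seed = 1)
  expect_lt(abs(mean(st$na) - 9), 1)
  expect_true(all(st$na >= 2 & st$na <= 15))
  # missingness: one pathological locus near 50%, others near the low rate
  expect_gt(max(st$md), 40)
  expect_lt(abs(mean(st$md[st$md < 40]) - 2), 2)
})

test_that("pedigree offspring are Mendelian-consistent when error-free", {
  fd <- parentage_founders(seed = 406, n = 30, n_ssr = 15)
  ped <- gen_pedigree(fd$table, n_trios = 20, error_rate = 0, seed = 407)
  fr <- suppressWarnings(allele_frequencies(ped$table))
  for (i in seq_len(5)) {
    res <- suppressWarnings(
      lod_parentage(ped$table, ped$truth$offspring[i], ped$truth$mother[i],
                    ped$truth$father[i], eps = 0, freqs = fr))
    expect_equal(res$mismatches, 0L)
    expect_gt(res$lod, 0)
  }
  # full selfing forces mother == father
  ped_s <- gen_pedigree(fd$table, n_trios = 10, selfing_rate = 1, seed = 408)
  expect_equal(ped_s$truth$mother, ped_s$truth$father)
})

test_that("error-driven mismatches match their analytic expectation", {
  fd <- parentage_founders(seed = 409, n = 60, n_ssr = 20)
  founders <- fd$table
  eps <- 0.05
  ped <- gen_pedigree(founders, n_trios = 300, error_rate = eps, seed = 410)
  loci <- panel_loci(gt_panel(founders), system = "SSR")
  fr <- allele_frequencies(founders, loci)
  # expectation: eps * sum over loci of P(random HW genotype incompatible
  # with the recorded parent pair), enumerated from the founder frequencies
  expect_per_trio <- vapply(seq_len(nrow(ped$truth)), function(i) {
    mo <- ped$truth$mother[i]; fa <- ped$truth$father[i]
    tot <- 0
    for (l in loci) {
      fl <- fr[fr$locus == l, ]
      p <- setNames(fl$freq, fl$allele)
      gm <- vinekin:::genotype_at(founders, mo, l)
      gf <- vinekin:::genotype_at(founders, fa, l)
      if (anyNA(gm) || anyNA(gf)) next
      al <- names(p)
      incompat <- 0
      for (a in seq_along(al)) for (b in seq(a, length(al))) {
        pg <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
        t2 <- transition_probability(c(al[a], al[b]), gm, gf, freqs = p, eps = 0)
        if (t2 == 0) incompat <- incompat + pg
      }
      tot <- tot + eps * incompat
    }
    tot
  }, 1)
  observed <- vapply(seq_len(nrow(ped$truth)), function(i) {
    suppressWarnings(
      lod_parentage(ped$table, ped$truth$offspring[i], ped$truth$mother[i],
                    ped$truth$father[i], loci = loci, eps = 0,
                    freqs = fr))$mismatches
  }, 1)
  expect_lt(abs(mean(observed) - mean(expect_per_trio)),
            3 * sd(observed) / sqrt(length(observed)) + 0.05)
})

test_that("planted clones respect the mutation budget and are recoverable", {
  sim <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 20, n_ssr = 10,
                                       n_snp = 0, n_cp = 0, seed = 411,
                                       high_missing_locus = FALSE,
                                       missing_rate = 0))
  cl0 <- gen_clones(sim$table, 2, n_mutations = 0, seed = 412)
  for (i in seq_len(nrow(cl0$truth))) {
    a <- tibble::as_tibble(cl0$table)[cl0$table$id == cl0$truth$id[i], -1]
    b <- tibble::as_tibble(cl0$table)[cl0$table$id == cl0$truth$clone_of[i], -1]
    expect_equal(a, b, ignore_attr = TRUE)
  }
  cl2 <- gen_clones(sim$table, 3, max_mutations = 2, seed = 413)
  for (i in seq_len(nrow(cl2$truth))) {
    mm <- pairwise_mismatch(cl2$table, cl2$truth$id[i], cl2$truth$clone_of[i])
    expect_lte(mm$allele_mismatches, 2L)
  }
})
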
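test_that("allele mismatches are counted as multisets per co-typed locus", {
  panel <- toy_ssr_panel(c("L1", "L2", "L3"))
  gt <- toy_table(list(
    id = c("a", "b", "c", "d"),
    L1_1 = c(123, 123, 123, NA), L1_2 = c(137, 137, 139, NA),
    L2_1 = c(100, 100, 100, NA), L2_2 = c(102, 102, 102, NA),
    L3_1 = c(123, 137, 200, NA), L3_2 = c(123, 139, 202, NA)), panel)
  expect_equal(pairwise_mismatch(gt, "a", "a")$allele_mismatches, 0L)
  # identical at L1/L2, homozygote vs disjoint heterozygote at L3
  mm <- pairwise_mismatch(gt, "a", "b")
  expect_equal(mm$loci_compared, 3L)
  expect_equal(mm$allele_mismatches, 0L + 0L + 2L)
  # (123,137) vs (123,139): one mismatching allele
  expect_equal(pairwise_mismatch(gt, "a", "c", loci = "L1")$allele_mismatches, 1L)
  # (123,123) vs (137,139): two mismatching alleles at one locus
  expect_equal(pairwise_mismatch(gt, "a", "b", loci = "L3")$allele_mismatches, 2L)
  expect_error(pairwise_mismatch(gt, "a", "d"), "incomparable")
})

test_that("duplicate grouping respects the two-allele tolerance", {
  sim <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 20, n_ssr = 9,
                                       n_snp = 0, n_cp = 0, seed = 301,
                                       high_missing_locus = FALSE,
                                       missing_rate = 0))
  # three planted clone groups within tolerance
  cl <- gen_clones(sim$table, 3, max_mutations = 2, seed = 302)
  rep <- find_duplicates(cl$table, loci = gt_panel(cl$table)$locus)
  grp <- rep$groups
  multi <- names(which(table(grp$group) > 1))
  expect_length(multi, 3)
  for (i in seq_len(nrow(cl$truth))) {
    expect_equal(grp$group[grp$id == cl$truth$id[i]],
                 grp$group[grp$id == cl$truth$clone_of[i]])
  }
  # representatives are deterministic and unique per group
  expect_equal(sum(grp$representative), length(unique(grp$group)))

  # a clone with three mutations stays separate (negative control)
  cl3 <- gen_clones(sim$table, 1, n_mutations = 3, seed = 303)
  rep3 <- find_duplicates(cl3$table, loci = gt_panel(cl3$table)$locus)
  g3 <- rep3$groups
  expect_false(g3$group[g3$id == cl3$truth$id] ==
               g3$group[g3$id == cl3$truth$clone_of])
})

test_that("zero tolerance reduces grouping to exact profile equality", {
  gt <- random_table(25, 6, n_alleles = 3, seed = 17)
  rep0 <- find_duplicates(gt, max_mismatch = 0)
  key <- apply(tibble::as_tibble(gt)[-1], 1, paste, collapse = "|")
  expect_equal(length(unique(rep0$groups$group)), length(unique(key)))
  for (k in unique(key)) {
    ids <- gt$id[key == k]
    expect_length(unique(rep0$groups$group[rep0$groups$id %in% ids]), 1)
  }
})

test_that("low-overlap pairs are reported but never merged", {
  panel <- toy_ssr_panel(c("L1", "L2"))
  gt <- toy_table(list(id = c("a", "b"),
                       L1_1 = c(123, 123), L1_2 = c(137, 137),
                       L2_1 = c(100, NA), L2_2 = c(102, NA)), panel)
  rep <- find_duplicates(gt, loci = c("L1", "L2"), min_overlap = 2)
  expect_equal(nrow(rep$pairs), 1)
  expect_false(rep$pairs$merged[1])
  expect_length(unique(rep$groups$group), 2)
})

test_that("status classification follows the nine-class cascade", {
  sim <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 8, n_ssr = 9,
                                       n_snp = 0, n_cp = 0, seed = 310,
                                       high_missing_locus = FALSE,
                                       missing_rate = 0))
  cl <- gen_clones(sim$table, 1, max_mutations = 0, seed = 311)
  rep <- find_duplicates(cl$table, loci = gt_panel(cl$table)$locus)
  ids <- rep$groups$id
  meta <- tibble::tibble(
    id = ids,
    intruder = ids == "acc002",
    mislabeled = ids == "acc003",
    sampling_error = ids == "acc004",
    documented_foreign = ids == "acc005",
    ampelographic_record = !ids %in% c("acc006", "acc002", "acc003", "acc004"))
  ext <- tibble::tibble(id = c("acc007", "acc008"),
                        match_id = c("x1", "x2"),
                        country = c("Italy", "Chile"),
                        neighbor = c(TRUE, FALSE))
  st <- classify_status(rep, meta, ext)
  lookup <- function(i) st$status[st$id == i]
  expect_equal(lookup("acc002"), "VI")
  expect_equal(lookup("acc003"), "VIII")
  expect_equal(lookup("acc004"), "IX")
  expect_equal(lookup("acc005"), "V")
  expect_equal(lookup("acc006"), "VII")     # unique, no ampelographic record
  expect_equal(lookup("acc007"), "III")     # synonym in a neighbouring country
  expect_equal(lookup("acc008"), "IV")      # synonym in a distant country
  expect_equal(lookup("acc001"), "I")       # unique with a full record
  # exact duplicate: the non-representative member is II
  dup <- cl$truth$id[1]
  expect_equal(lookup(dup), "II")
  # conflicting flags -> unresolved, with a warning
  meta2 <- meta
  meta2$mislabeled[meta2$id == "acc002"] <- TRUE
  expect_warning(st2 <- classify_status(rep, meta2, ext), "Conflicting")
  expect_equal(st2$status[st2$id == "acc002"], "unresolved")
})
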
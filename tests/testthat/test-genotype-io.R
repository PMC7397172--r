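test_that("genotype CSV parsing handles combined cells, sorting and missing codes", {
  panel <- toy_ssr_panel("L1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1", "a,123/137", "b,"), path)
  gt <- suppressMessages(read_genotype_csv(path, panel))
  expect_equal(gt$L1_1, c(123L, NA))
  expect_equal(gt$L1_2, c(137L, NA))
  expect_equal(attr(gt, "n_missing")[["L1"]], 1L)

  writeLines(c("id,L1", "a,\"137,123\""), path)
  gt2 <- suppressMessages(read_genotype_csv(path, panel))
  expect_equal(c(gt2$L1_1, gt2$L1_2), c(123L, 137L))
})

test_that("half-typed cells are rejected with the locus named", {
  panel <- toy_ssr_panel("L1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2", "a,123,", "b,100,102"), path)
  expect_error(suppressMessages(read_genotype_csv(path, panel)), "L1")
})

test_that("alleles outside the expected range warn but are retained", {
  panel <- marker_panel("L1", "SSR", 2, "cat1", range_min = 100, range_max = 150)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2", "a,98,120"), path)
  expect_warning(gt <- suppressMessages(read_genotype_csv(path, panel)),
                 "outside expected range")
  expect_equal(gt$L1_1, 98L)
})

test_that("a 127 x 36 synthetic table round-trips through CSV unchanged", {
  sim <- gen_population(sim_pop_config(seed = 77))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(sim$table, path)
  back <- suppressMessages(read_genotype_csv(path, gt_panel(sim$table)))
  orig <- tibble::as_tibble(sim$table)[, names(tibble::as_tibble(back))]
  expect_equal(tibble::as_tibble(back), orig, ignore_attr = TRUE)
})

test_that("STRUCTURE export uses two rows, -9 for missing, distinct codes", {
  panel <- toy_ssr_panel("L1")
  gt <- toy_table(list(id = c("a", "b"), L1_1 = c(123L, NA), L1_2 = c(137L, NA)),
                  panel)
  txt <- write_structure_format(gt)
  expect_length(txt, 4)
  expect_match(txt[1], "^a 1$")
  expect_match(txt[2], "^a 2$")
  expect_match(txt[3], "^b -9$")
  expect_error(write_structure_format(gt, loci = "nope"))
})

test_that("STRUCTURE recode is bijective on random tables", {
  for (seed in 1:3) {
    gt <- random_table(15, 4, n_alleles = 6, seed = seed, missing_rate = 0.1)
    dec <- decode_structure(write_structure_format(gt))
    expect_equal(tibble::as_tibble(dec),
                 tibble::as_tibble(gt)[, names(tibble::as_tibble(dec))],
                 ignore_attr = TRUE)
  }
})

test_that("cpSSR tables are rejected by the diploid STRUCTURE writer", {
  panel <- marker_panel(c("L1", "cp1"), c("SSR", "cpSSR"),
                        motif_length = c(2, 1), category = c("cat1", "cat4"))
  gt <- genotype_table(tibble::tibble(id = "a", L1_1 = 1L, L1_2 = 2L, cp1 = 106L),
                       panel)
  expect_error(write_structure_format(gt, loci = c("L1", "cp1")), "cpSSR")
})

test_that("allele harmonization estimates modal offsets and flags inconsistency", {
  panel <- toy_ssr_panel(c("L1", "L2"))
  gt <- toy_table(list(id = c("a", "b", "c"),
                       L1_1 = c(123, 125, 123), L1_2 = c(137, 137, 123),
                       L2_1 = c(200, 202, 204), L2_2 = c(204, 206, 204)), panel)
  ref <- toy_table(list(id = c("a", "b", "c"),
                        L1_1 = c(121, 123, 121), L1_2 = c(135, 135, 121),
                        L2_1 = c(200, 202, 204), L2_2 = c(204, 206, 204)), panel)
  h <- harmonize_alleles(gt, ref)
  rep <- harmonization_report(h)
  expect_equal(rep$offset_applied, c(-2L, 0L))
  expect_equal(rep$agreement, c(1, 1))
  expect_equal(h$L1_1, ref$L1_1)

  # second application changes nothing (idempotent)
  h2 <- harmonize_alleles(h, ref)
  expect_equal(tibble::as_tibble(h2)[-1], tibble::as_tibble(h)[-1],
               ignore_attr = TRUE)

  # mixed offsets {+2, +2, +3}: modal agreement 2/3 < 0.8 -> flagged, unshifted
  gt3 <- toy_table(list(id = c("a", "b", "c"),
                        L1_1 = c(123, 125, 124), L1_2 = c(123, 125, 124),
                        L2_1 = c(200, 202, 204), L2_2 = c(200, 202, 204)), panel)
  ref3 <- toy_table(list(id = c("a", "b", "c"),
                         L1_1 = c(121, 123, 121), L1_2 = c(121, 123, 121),
                         L2_1 = c(200, 202, 204), L2_2 = c(200, 202, 204)), panel)
  h3 <- harmonize_alleles(gt3, ref3)
  r3 <- harmonization_report(h3)
  expect_equal(r3$flagged[1], "inconsistent")
  expect_equal(r3$offset_applied[1], 0L)
  expect_equal(h3$L1_1, gt3$L1_1)
})

test_that("allele binning merges close size classes and keeps modal sizes", {
  panel <- marker_panel(c("L1", "L2"), "SSR", 3, "cat1")
  gt <- genotype_table(tibble::tibble(
    id = c("a", "b", "c", "d"),
    L1_1 = c(246L, 247L, 249L, 247L), L1_2 = c(246L, 247L, 249L, 247L),
    L2_1 = c(123L, 126L, 129L, 126L), L2_2 = c(123L, 126L, 129L, 126L)), panel)
  b <- bin_alleles(gt, "L1", 3)
  # one class {246, 247, 249}; 247 is modal (3 copies)
  expect_equal(unique(c(b$L1_1, b$L1_2)), 247L)
  # gaps equal to the spacing are NOT merged
  b2 <- bin_alleles(gt, "L2", 3)
  expect_equal(sort(unique(c(b2$L2_1, b2$L2_2))), c(123L, 126L, 129L))
  # single observed allele is untouched
  one <- genotype_table(tibble::tibble(id = "a", L1_1 = 200L, L1_2 = 200L,
                                       L2_1 = 101L, L2_2 = 101L), panel)
  expect_equal(bin_alleles(one, "L1")$L1_1, 200L)
})

test_that("binning never increases the number of distinct alleles", {
  for (seed in 1:4) {
    gt <- random_table(20, 3, n_alleles = 8, seed = seed)
    for (l in gt_panel(gt)$locus) {
      before <- length(unique(stats::na.omit(c(gt[[paste0(l, "_1")]],
                                               gt[[paste0(l, "_2")]]))))
      b <- bin_alleles(gt, l, 2)
      after <- length(unique(stats::na.omit(c(b[[paste0(l, "_1")]],
                                              b[[paste0(l, "_2")]]))))
      expect_lte(after, before)
    }
  }
})
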
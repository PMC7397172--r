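#' Allele mismatches between two accessions
#'
#' At each locus typed in both accessions the mismatch count is
#' `2 - |multiset intersection of the two allele pairs|`, i.e. 0 for equal
#' genotypes, 1 when exactly one allele is shared (counting homozygotes as
#' two copies), 2 for disjoint genotypes. Counts are summed over loci.
#'
#' @param gt Genotype table.
#' @param id_a,id_b Accession ids to compare.
#' @param loci Loci to use; default all nuclear loci.
#' @return A one-row tibble with `loci_compared` and `allele_mismatches`.
#' @export
pairwise_mismatch <- function(gt, id_a, id_b, loci = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  al <- gt_alleles(gt, loci)
  ia <- match(id_a, gt$id); ib <- match(id_b, gt$id)
  if (is.na(ia) || is.na(ib)) abort("Unknown accession id.")
  mm <- mismatch_vectors(al$a1[ia, ], al$a2[ia, ], al$a1[ib, ], al$a2[ib, ])
  if (mm[["loci_compared"]] == 0L) {
    abort(paste0("Accessions ", id_a, " and ", id_b,
                 " share no typed locus: incomparable."))
  }
  tibble(id_a = id_a, id_b = id_b,
         loci_compared = mm[["loci_compared"]],
         allele_mismatches = mm[["allele_mismatches"]])
}

# vectorised over loci: x1/x2 and y1/y2 are allele vectors (sorted pairs)
mismatch_vectors <- function(x1, x2, y1, y2) {
  ok <- !is.na(x1) & !is.na(y1)
  shared <- shared_alleles(x1[ok], x2[ok], y1[ok], y2[ok])
  c(loci_compared = sum(ok), allele_mismatches = sum(2L - shared))
}

# multiset intersection size of two sorted allele pairs, vectorised.
# For sorted pairs (x1<=x2, y1<=y2) the multiset intersection is 2 iff the
# pairs are equal; otherwise 1 iff any cross-match exists; else 0.
shared_alleles <- function(x1, x2, y1, y2) {
  eq <- (x1 == y1) & (x2 == y2)
  any1 <- (x1 == y1) | (x1 == y2) | (x2 == y1) | (x2 == y2)
  ifelse(eq, 2L, ifelse(any1, 1L, 0L))
}

#' Find duplicate accessions and identity groups
#'
#' Two accessions are duplicates when their profiles differ by at most
#' `max_mismatch` alleles over the comparison loci (tolerating genotyping
#' errors and somatic mutations in clonally propagated material). Identity
#' groups are the transitive closure of the duplicate relation; pairs with
#' fewer than `min_overlap` co-typed loci are reported but never merged.
#'
#' @param gt Genotype table.
#' @param loci Comparison loci; default the `cat1` fingerprinting panel.
#' @param max_mismatch Allele-mismatch tolerance (default 2).
#' @param min_overlap Minimal co-typed loci for a pair to be mergeable;
#'   default two thirds of the panel, capped at 6 (6 of the 9-locus
#'   fingerprinting set).
#' @param true_to_type Optional character vector of accession ids whose
#'   profile is authenticated; preferred as group representatives.
#' @return A `vk_match_report`: list with `pairs` (all pairs at or below
#'   the tolerance, plus low-overlap pairs flagged), `groups` (tibble
#'   `id`, `group`, `representative`), and `non_clique_groups`.
#' @export
find_duplicates <- function(gt, loci = NULL, max_mismatch = 2,
                            min_overlap = NULL, true_to_type = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% {
    l <- panel_loci(panel, category = "cat1")
    if (length(l) == 0) nuclear_loci(panel) else l
  }
  min_overlap <- min_overlap %||% min(6L, ceiling(2 * length(loci) / 3))
  al <- gt_alleles(gt, loci)
  n <- nrow(gt)
  ids <- gt$id
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  rows <- list(); k <- 0L
  for (i in seq_len(n - 1)) {
    x1 <- al$a1[i, ]; x2 <- al$a2[i, ]
    for (j in (i + 1):n) {
      ok <- !is.na(x1) & !is.na(al$a1[j, ])
      lc <- sum(ok)
      if (lc == 0L) next
      mm <- sum(2L - shared_alleles(x1[ok], x2[ok], al$a1[j, ok], al$a2[j, ok]))
      if (mm <= max_mismatch) {
        merged <- lc >= min_overlap
        if (merged) union_(i, j)
        k <- k + 1L
        rows[[k]] <- tibble(id_a = ids[i], id_b = ids[j], loci_compared = lc,
                            allele_mismatches = mm, merged = merged)
      }
    }
  }
  pairs <- if (k) bind_rows(rows) else
    tibble(id_a = character(), id_b = character(), loci_compared = integer(),
           allele_mismatches = integer(), merged = logical())
  root <- vapply(seq_len(n), find, 1L)
  grp <- match(root, unique(root))
  groups <- tibble(id = ids, group = grp) |>
    group_by(.data$group) |>
    mutate(representative = .data$id == pick_representative(.data$id, true_to_type)) |>
    ungroup()
  # groups where not every member pair is itself within tolerance
  non_clique <- vapply(split(seq_len(n), grp), function(ix) {
    if (length(ix) < 3) return(FALSE)
    cmb <- combn(ix, 2)
    npair <- sum(vapply(seq_len(ncol(cmb)), function(c2) {
      a <- cmb[1, c2]; b <- cmb[2, c2]
      any(pairs$merged & ((pairs$id_a == ids[a] & pairs$id_b == ids[b]) |
                          (pairs$id_a == ids[b] & pairs$id_b == ids[a])))
    }, TRUE))
    npair < ncol(cmb)
  }, TRUE)
  structure(list(pairs = pairs, groups = groups,
                 non_clique_groups = which(non_clique),
                 loci = loci, max_mismatch = max_mismatch),
            class = "vk_match_report")
}

pick_representative <- function(ids, true_to_type) {
  ttt <- intersect(sort(ids), true_to_type %||% character())
  if (length(ttt)) ttt[1] else sort(ids)[1]
}

#' @export
print.vk_match_report <- function(x, ...) {
  ng <- length(unique(x$groups$group))
  multi <- sum(table(x$groups$group) > 1)
  cat("# Identity analysis over ", length(x$loci), " loci (tolerance ",
      x$max_mismatch, " alleles)\n", sep = "")
  cat("# ", nrow(x$groups), " accessions -> ", ng, " identity groups (",
      multi, " with duplicates)\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.vk_match_report <- function(x, ...) x$groups

#' Assign the nine-class curation status to each accession
#'
#' Deterministic rule cascade over the identity groups, accession metadata
#' and matches against external databases:
#' \itemize{
#' \item conflicting curation flags -> `"unresolved"`;
#' \item `sampling_error` -> IX; `mislabeled` -> VIII; `intruder` -> VI;
#' \item non-representative member of a multi-accession identity group -> II;
#' \item external profile match in a neighbouring country -> III, in a
#'   distant country -> IV;
#' \item documented foreign origin -> V;
#' \item otherwise I with a full ampelographic record, else VII
#'   (questionable varietal status).
#' }
#'
#' @param report A [find_duplicates()] result.
#' @param metadata Tibble with column `id` and optional logical columns
#'   `intruder`, `mislabeled`, `sampling_error`, `documented_foreign`,
#'   `ampelographic_record`.
#' @param external_matches Optional tibble with columns `id`, `match_id`,
#'   `country`, `neighbor` (logical).
#' @return Tibble `id`, `status` (`"I"`..`"IX"` or `"unresolved"`).
#' @export
classify_status <- function(report, metadata, external_matches = NULL) {
  g <- report$groups
  meta <- left_join(g, metadata, by = "id")
  flag <- function(col) {
    v <- meta[[col]] %||% rep(FALSE, nrow(meta))
    !is.na(v) & v
  }
  intr <- flag("intruder"); misl <- flag("mislabeled"); samp <- flag("sampling_error")
  forn <- flag("documented_foreign"); ampel <- flag("ampelographic_record")
  grp_sizes <- table(meta$group)
  in_multi <- grp_sizes[as.character(meta$group)] > 1
  ext_nb <- ext_far <- rep(FALSE, nrow(meta))
  if (!is.null(external_matches) && nrow(external_matches)) {
    ext_nb <- meta$id %in% external_matches$id[external_matches$neighbor]
    ext_far <- meta$id %in% external_matches$id[!external_matches$neighbor]
  }
  status <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    nflags <- sum(intr[i], misl[i], samp[i])
    status[i] <-
      if (nflags > 1) "unresolved"
      else if (samp[i]) "IX"
      else if (misl[i]) "VIII"
      else if (intr[i]) "VI"
      else if (in_multi[i] && !meta$representative[i]) "II"
      else if (ext_nb[i]) "III"
      else if (ext_far[i]) "IV"
      else if (forn[i]) "V"
      else if (ampel[i]) "I"
      else "VII"
  }
  if (any(status == "unresolved")) {
    warn(paste0("Conflicting curation flags for: ",
                paste(meta$id[status == "unresolved"], collapse = ", ")))
  }
  tibble(id = meta$id, status = status)
}
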
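#' Harmonize allele sizes against reference profiles
#'
#' Sizing offsets between labs (different machines, M13-tailed primers) shift
#' every allele at a locus by a constant number of base pairs. For each SSR
#' locus this estimates that shift from accessions genotyped in both tables:
#' within each shared accession the sorted allele pair is matched
#' elementwise and the differences observed - reference are pooled. The
#' modal difference is taken as the locus offset (the mode, not the mean, so
#' a single mistyped reference cannot drag the locus), and `-offset` is
#' applied to every allele at the locus. Loci where the modal difference
#' accounts for less than `min_agreement` of the comparisons are flagged
#' `"inconsistent"` and left unshifted.
#'
#' @param gt Genotype table to adjust.
#' @param reference Genotype table holding reference profiles (same locus
#'   names).
#' @param shared_ids Accessions present in both tables to estimate from;
#'   default the intersection of ids.
#' @param min_agreement Minimal fraction of comparisons matching the modal
#'   difference (default 0.8).
#' @return The adjusted table, with a per-locus report tibble (columns
#'   `locus`, `offset_applied`, `agreement`, `n_comparisons`, `flagged`)
#'   attached as attribute `"harmonization"` (see
#'   [harmonization_report()]).
#' @export
harmonize_alleles <- function(gt, reference, shared_ids = NULL,
                              min_agreement = 0.8) {
  panel <- gt_panel(gt)
  loci <- panel$locus[panel$system == "SSR"]
  shared_ids <- shared_ids %||% intersect(gt$id, reference$id)
  rep_rows <- lapply(loci, function(loc) {
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!all(c(c1, c2) %in% names(reference))) {
      return(tibble(locus = loc, offset_applied = 0L, agreement = NA_real_,
                    n_comparisons = 0L, flagged = "no_reference"))
    }
    io <- match(shared_ids, gt$id); ir <- match(shared_ids, reference$id)
    d <- c(gt[[c1]][io] - reference[[c1]][ir],
           gt[[c2]][io] - reference[[c2]][ir])
    d <- d[!is.na(d)]
    if (length(d) < 4) {  # need >=2 fully typed shared accessions
      return(tibble(locus = loc, offset_applied = 0L, agreement = NA_real_,
                    n_comparisons = length(d), flagged = "too_few_references"))
    }
    tab <- table(d)
    best <- as.integer(names(tab)[which.max(tab)])  # ties -> first = smallest
    agree <- max(tab) / length(d)
    if (agree < min_agreement) {
      tibble(locus = loc, offset_applied = 0L, agreement = agree,
             n_comparisons = length(d), flagged = "inconsistent")
    } else {
      tibble(locus = loc, offset_applied = -best, agreement = agree,
             n_comparisons = length(d), flagged = "ok")
    }
  })
  report <- bind_rows(rep_rows)
  for (i in seq_len(nrow(report))) {
    off <- report$offset_applied[i]
    if (off != 0L) {
      loc <- report$locus[i]
      c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
      gt[[c1]] <- gt[[c1]] + off
      gt[[c2]] <- gt[[c2]] + off
    }
  }
  attr(gt, "harmonization") <- report
  gt
}

#' Retrieve the report attached by [harmonize_alleles()]
#' @param gt A harmonized genotype table.
#' @return The per-locus offset report tibble.
#' @export
harmonization_report <- function(gt) {
  r <- attr(gt, "harmonization")
  if (is.null(r)) abort("No harmonization report: run harmonize_alleles() first.")
  r
}

#' Bin SSR allele sizes into allelic classes
#'
#' Raw fragment sizes scatter around the repeat ladder. Observed sizes at a
#' locus are clustered by single linkage: sizes whose gap to the nearest
#' neighbour is strictly less than `class_spacing` fall in one class, and
#' every member is replaced by the class's modal size (ties broken toward
#' the smallest). Off-ladder singletons -- genuine one-bp variants --
#' survive as their own class.
#'
#' @param gt Genotype table.
#' @param locus Locus name to bin.
#' @param class_spacing Base-pair spacing of allelic classes (1, 2 or 3);
#'   default the locus's motif length.
#' @return The table with the locus's alleles replaced by class
#'   representatives.
#' @export
bin_alleles <- function(gt, locus, class_spacing = NULL) {
  panel <- gt_panel(gt)
  if (!locus %in% panel$locus) abort(paste0("Unknown locus: ", locus))
  class_spacing <- class_spacing %||% panel$motif_length[panel$locus == locus]
  if (is.na(class_spacing) || !class_spacing %in% 1:3) {
    abort("class_spacing must be 1, 2 or 3 (or a motif length in that range).")
  }
  c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
  sizes <- c(gt[[c1]], gt[[c2]])
  obs <- sort(unique(sizes[!is.na(sizes)]))
  if (length(obs) <= 1) return(gt)
  # single linkage on the integer line: break where gap >= spacing
  grp <- cumsum(c(1L, as.integer(diff(obs) >= class_spacing)))
  counts <- table(factor(sizes, levels = obs))
  remap <- unlist(lapply(split(seq_along(obs), grp), function(ix) {
    cnt <- counts[ix]
    rep_size <- obs[ix][which.max(cnt)]  # which.max: first max = smallest size
    setNames(rep(rep_size, length(ix)), obs[ix])
  }))
  names(remap) <- unlist(lapply(split(obs, grp), as.character))
  gt[[c1]] <- unname(remap[as.character(gt[[c1]])])
  gt[[c2]] <- unname(remap[as.character(gt[[c2]])])
  gt
}
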
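#' Proportion-of-shared-alleles distance matrix
#'
#' For each accession pair, PSA is the number of shared alleles (multiset
#' intersection per co-typed locus, so a homozygote shares at most one
#' allele with a heterozygote carrying it) divided by twice the number of
#' co-typed loci, and the dissimilarity is d = -ln(PSA). Missing loci are
#' pairwise-deleted; pairs with fewer than `min_overlap` co-typed loci are
#' marked unavailable. Fully disjoint pairs (PSA = 0) are capped at
#' ln(4L) -- below any observable finite distance would be infinite -- and
#' flagged.
#'
#' @param gt Genotype table.
#' @param loci Loci to use; default all nuclear loci.
#' @param min_overlap Minimal co-typed loci per pair; default
#'   `ceiling(L/2)`.
#' @return A `vk_dist` object: list with `d` (symmetric matrix, `NA` where
#'   unavailable), `overlap` (co-typed locus counts), `capped` (logical
#'   matrix), `cap`, `ids`.
#' @export
psa_distance <- function(gt, loci = NULL, min_overlap = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  L <- length(loci)
  min_overlap <- min_overlap %||% ceiling(L / 2)
  al <- gt_alleles(gt, loci)
  n <- nrow(gt)
  d <- matrix(0, n, n, dimnames = list(gt$id, gt$id))
  overlap <- matrix(L, n, n, dimnames = dimnames(d))
  capped <- matrix(FALSE, n, n, dimnames = dimnames(d))
  cap <- log(4 * L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(al$a1[i, ]) & !is.na(al$a1[j, ])
      lc <- sum(ok)
      overlap[i, j] <- overlap[j, i] <- lc
      if (lc < min_overlap) { d[i, j] <- d[j, i] <- NA_real_; next }
      sh <- sum(shared_alleles(al$a1[i, ok], al$a2[i, ok],
                               al$a1[j, ok], al$a2[j, ok]))
      psa <- sh / (2 * lc)
      if (psa == 0) {
        d[i, j] <- d[j, i] <- cap
        capped[i, j] <- capped[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- min(-log(psa), cap)
      }
    }
  }
  structure(list(d = d, overlap = overlap, capped = capped, cap = cap,
                 ids = gt$id, min_overlap = min_overlap),
            class = "vk_dist")
}

#' @export
print.vk_dist <- function(x, ...) {
  cat("# -ln(PSA) distance matrix: ", length(x$ids), " accessions",
      if (any(is.na(x$d))) " (incomplete: low-overlap pairs present)" else "",
      "\n", sep = "")
  print(round(x$d[seq_len(min(6, nrow(x$d))), seq_len(min(6, ncol(x$d)))], 4))
  invisible(x)
}

#' @export
tidy.vk_dist <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(id_a = x$ids[ut[, 1]], id_b = x$ids[ut[, 2]],
         distance = x$d[ut], co_typed_loci = x$overlap[ut],
         capped = x$capped[ut])
}

#' UPGMA clustering of a distance matrix
#'
#' Standard average-linkage agglomeration: the closest pair of clusters is
#' merged at a node of height half their average distance, and
#' between-cluster distances are size-weighted averages. Ties are broken
#' deterministically toward the pair whose smallest member ids sort first.
#' The result is ultrametric by construction.
#'
#' @param dm A `vk_dist` (complete: no `NA` cells) or a base matrix/dist.
#' @return A `vk_upgma`: list with `phylo` (an [ape::phylo] tree with
#'   branch lengths), `height` (root height), `newick`.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "vk_dist")) {
    if (any(is.na(dm$d))) {
      abort("Distance matrix incomplete (pairs below the overlap guard); cannot cluster.")
    }
    d <- dm$d
  } else if (inherits(dm, "dist")) {
    d <- as.matrix(dm)
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  ids <- rownames(d) %||% as.character(seq_len(n))
  if (n < 2) abort("Need at least two accessions to cluster.")
  # active clusters: list of member indices; newick labels; heights
  members <- as.list(seq_len(n))
  label <- vapply(ids, newick_quote, "")
  height <- rep(0, n)
  key <- ids  # tie-break key: smallest member id of each cluster
  active <- seq_len(n)
  D <- d
  for (step in seq_len(n - 1)) {
    # find min distance among active pairs with deterministic tie-break
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        dd <- D[a, b]
        if (dd < best_d - 1e-12) {
          best <- c(a, b); best_d <- dd
        } else if (abs(dd - best_d) <= 1e-12 && !is.null(best)) {
          cand <- sort(c(key[a], key[b])); cur <- sort(c(key[best[1]], key[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(a, b); best_d <- dd
          }
        }
      }
    }
    a <- best[1]; b <- best[2]
    h <- best_d / 2
    na_ <- length(members[[a]]); nb <- length(members[[b]])
    new_label <- paste0("(", label[a], ":", fmt_bl(h - height[a]), ",",
                        label[b], ":", fmt_bl(h - height[b]), ")")
    # size-weighted average linkage update
    for (c_ in setdiff(active, c(a, b))) {
      D[a, c_] <- D[c_, a] <- (na_ * D[a, c_] + nb * D[b, c_]) / (na_ + nb)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    label[a] <- new_label
    height[a] <- h
    key[a] <- min(key[a], key[b])
    active <- setdiff(active, b)
  }
  root <- active[1]
  newick <- paste0(label[root], ";")
  phylo <- ape::read.tree(text = newick)
  structure(list(phylo = phylo, height = height[root], newick = newick),
            class = "vk_upgma")
}

fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

newick_quote <- function(x) {
  if (grepl("[][ ():;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Newick text for a UPGMA tree
#'
#' Branch lengths are height differences between parent and child nodes;
#' labels containing spaces or Newick metacharacters are quoted.
#'
#' @param tree A `vk_upgma` (or an [ape::phylo]).
#' @return Single Newick string.
#' @export
to_newick <- function(tree) {
  if (inherits(tree, "vk_upgma")) return(tree$newick)
  if (inherits(tree, "phylo")) return(ape::write.tree(tree))
  abort("Not a tree.")
}

#' @export
print.vk_upgma <- function(x, ...) {
  cat("# UPGMA tree: ", length(x$phylo$tip.label), " tips, root height ",
      signif(x$height, 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.vk_upgma <- function(x, ...) plot(x$phylo, ...)
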
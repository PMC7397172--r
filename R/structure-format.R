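#' Export a genotype table in STRUCTURE two-row format
#'
#' Each nuclear diploid individual becomes two rows: the id followed by one
#' integer-recoded allele per locus, with `-9` for missing. The integer
#' recode (per-locus allele -> code key) is attached as the `"key"`
#' attribute, so the encoding is invertible via [decode_structure()].
#'
#' @param gt A `vk_geno` table with nuclear loci only (cpSSR loci are
#'   rejected: the two-row format is diploid).
#' @param loci Loci to export; default all nuclear loci of the panel.
#' @return Character vector of lines (one header comment plus two lines per
#'   individual), with attributes `"key"` (named list of allele vectors)
#'   and `"loci"`.
#' @export
write_structure_format <- function(gt, loci = NULL) {
  panel <- gt_panel(gt)
  if (is.null(loci)) loci <- nuclear_loci(panel)
  if (any(loci %in% cp_loci(panel))) {
    abort("cpSSR loci cannot be written in the diploid two-row format.")
  }
  key <- lapply(loci, function(l) {
    sort(unique(stats::na.omit(c(gt[[paste0(l, "_1")]], gt[[paste0(l, "_2")]]))))
  })
  names(key) <- loci
  enc <- function(side) {
    sapply(loci, function(l) {
      code <- match(gt[[paste0(l, "_", side)]], key[[l]])
      ifelse(is.na(code), -9L, code)
    })
  }
  e1 <- enc(1); e2 <- enc(2)
  if (nrow(gt) == 1) { e1 <- matrix(e1, 1); e2 <- matrix(e2, 1) }
  lines <- character(2 * nrow(gt))
  for (i in seq_len(nrow(gt))) {
    lines[2 * i - 1] <- paste(c(gt$id[i], e1[i, ]), collapse = " ")
    lines[2 * i]     <- paste(c(gt$id[i], e2[i, ]), collapse = " ")
  }
  structure(lines, key = key, loci = loci, panel = panel)
}

#' Decode STRUCTURE-format text back into a genotype table
#'
#' Inverse of [write_structure_format()] given its attached recode key.
#'
#' @param lines Output of [write_structure_format()] (attributes intact).
#' @return A `vk_geno` table.
#' @export
decode_structure <- function(lines) {
  key <- attr(lines, "key"); loci <- attr(lines, "loci")
  panel <- attr(lines, "panel")
  if (is.null(key) || is.null(loci)) {
    abort("decode_structure() needs the key/loci attributes written by write_structure_format().")
  }
  toks <- stringr::str_split(lines, " +")
  n <- length(lines) / 2
  df <- tibble(id = vapply(toks[2 * seq_len(n) - 1], `[[`, "", 1))
  for (j in seq_along(loci)) {
    l <- loci[j]
    c1 <- vapply(toks[2 * seq_len(n) - 1], function(t) as.integer(t[j + 1]), 1L)
    c2 <- vapply(toks[2 * seq_len(n)], function(t) as.integer(t[j + 1]), 1L)
    dec <- function(code) {
      out <- key[[l]][ifelse(code == -9L, NA_integer_, code)]
      out
    }
    a1 <- dec(c1); a2 <- dec(c2)
    df[[paste0(l, "_1")]] <- pmin(a1, a2)
    df[[paste0(l, "_2")]] <- pmax(a1, a2)
  }
  sub_panel <- panel[panel$locus %in% loci, , drop = FALSE]
  genotype_table(df, sub_panel)
}
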
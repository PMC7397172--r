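#' Genotype tables
#'
#' A genotype table is a wide tibble with one row per accession: an `id`
#' column, two columns `<locus>_1`, `<locus>_2` per nuclear (diploid) locus
#' holding the unordered allele pair sorted ascending, and a single
#' `<locus>` column per haploid cpSSR locus. Missing data is whole-cell:
#' both alleles `NA` or neither. The marker panel travels along as the
#' `"panel"` attribute.
#'
#' @param df Data frame with an `id` column and allele columns as above.
#' @param panel A [marker_panel()] describing the loci.
#' @return A tibble of class `vk_geno`.
#' @export
genotype_table <- function(df, panel) {
  panel <- validate_marker_panel(panel)
  df <- as_tibble(df)
  if (!"id" %in% names(df)) abort("Genotype table needs an `id` column.")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) abort("Accession ids must be unique.")
  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    if (panel$system[i] == "cpSSR") {
      if (!loc %in% names(df)) abort(paste0("Missing cpSSR column: ", loc))
      next
    }
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!all(c(c1, c2) %in% names(df))) {
      abort(paste0("Missing allele columns for locus ", loc, " (", c1, ", ", c2, ")."))
    }
    a1 <- df[[c1]]; a2 <- df[[c2]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      abort(paste0("Half-typed cell(s) at locus ", loc, ", row(s) ",
                   paste(which(half), collapse = ", "),
                   ": one allele present, one missing."))
    }
    # store the unordered pair sorted ascending
    swap <- !is.na(a1) & !is.na(a2) & a2 < a1
    if (any(swap)) {
      tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
      df[[c1]] <- a1; df[[c2]] <- a2
    }
  }
  keep <- c("id", unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$system[i] == "cpSSR") panel$locus[i]
    else paste0(panel$locus[i], c("_1", "_2"))
  })))
  extra <- setdiff(names(df), keep)
  df <- df[, c(keep, extra)]
  attr(df, "panel") <- panel
  class(df) <- unique(c("vk_geno", class(df)))
  df
}

#' @export
`[.vk_geno` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && is.null(attr(out, "panel"))) {
    attr(out, "panel") <- attr(x, "panel")
  }
  out
}

#' @export
print.vk_geno <- function(x, ...) {
  panel <- attr(x, "panel")
  cat("# Genotype table: ", nrow(x), " accessions x ", nrow(panel),
      " loci (", sum(panel$system == "SSR"), " SSR, ",
      sum(panel$system == "SNP"), " SNP, ",
      sum(panel$system == "cpSSR"), " cpSSR)\n", sep = "")
  NextMethod()
}

#' Extract the marker panel of a genotype table
#' @param gt A `vk_geno` table.
#' @return The `vk_panel` attribute.
#' @export
gt_panel <- function(gt) {
  p <- attr(gt, "panel")
  if (is.null(p)) abort("This table carries no marker panel.")
  validate_marker_panel(p)
}

# allele matrices for a set of nuclear loci: list(a1, a2), n x L character
# matrices (alleles as labels), rownames = ids
gt_alleles <- function(gt, loci) {
  a1 <- sapply(loci, function(l) as.character(gt[[paste0(l, "_1")]]))
  a2 <- sapply(loci, function(l) as.character(gt[[paste0(l, "_2")]]))
  if (nrow(gt) == 1) { a1 <- matrix(a1, nrow = 1, dimnames = list(NULL, loci))
                       a2 <- matrix(a2, nrow = 1, dimnames = list(NULL, loci)) }
  rownames(a1) <- rownames(a2) <- gt$id
  list(a1 = a1, a2 = a2)
}

#' Read a genotype CSV file
#'
#' The CSV dialect has one row per accession and an `id` column. Nuclear
#' loci occupy either two columns `<locus>_1`, `<locus>_2` or a single
#' `<locus>` column with the two alleles separated by `/` or `,`
#' (homozygotes written `a/a`). cpSSR loci always use one single-valued
#' column. Empty cells, `NA` and `0` denote missing data (whole cell).
#' Half-typed cells are rejected; alleles outside a locus's expected range
#' raise a warning but are retained.
#'
#' @param path CSV file path.
#' @param panel A [marker_panel()].
#' @return A `vk_geno` genotype table; the per-locus count of missing cells
#'   is reported via a message.
#' @export
read_genotype_csv <- function(path, panel) {
  panel <- validate_marker_panel(panel)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  parse_genotype_df(raw, panel)
}

parse_genotype_df <- function(raw, panel) {
  if (!"id" %in% names(raw)) abort("Genotype CSV needs an `id` column.")
  out <- tibble(id = as.character(raw$id))
  n_missing <- integer(nrow(panel))
  names(n_missing) <- panel$locus
  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    sys <- panel$system[i]
    if (sys == "cpSSR") {
      if (!loc %in% names(raw)) abort(paste0("Missing column for cpSSR locus ", loc, "."))
      v <- clean_allele(raw[[loc]])
      out[[loc]] <- as_allele(v, sys)
      n_missing[i] <- sum(is.na(v))
      next
    }
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (all(c(c1, c2) %in% names(raw))) {
      a1 <- clean_allele(raw[[c1]]); a2 <- clean_allele(raw[[c2]])
    } else if (loc %in% names(raw)) {
      parts <- stringr::str_split(clean_allele(raw[[loc]]), "[/,]", n = 2)
      a1 <- clean_allele(vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, ""))
      a2 <- clean_allele(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""))
    } else {
      abort(paste0("No columns found for nuclear locus ", loc, "."))
    }
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      abort(paste0("Half-typed cell at locus ", loc, ", row(s) ",
                   paste(which(half), collapse = ", "), "."))
    }
    a1 <- as_allele(a1, sys); a2 <- as_allele(a2, sys)
    check_range(c(a1, a2), panel[i, ])
    out[[c1]] <- a1; out[[c2]] <- a2
    n_missing[i] <- sum(is.na(a1))
  }
  inform(paste0("Read ", nrow(out), " accessions; missing cells per locus: ",
                paste0(names(n_missing), "=", n_missing, collapse = ", ")))
  gt <- genotype_table(out, panel)
  attr(gt, "n_missing") <- n_missing
  gt
}

clean_allele <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[x %in% the_missing_codes] <- NA_character_
  x
}

as_allele <- function(x, system) {
  if (system == "SNP") {
    x <- toupper(x)
    bad <- !is.na(x) & !x %in% c("A", "C", "G", "T")
    if (any(bad)) abort(paste0("SNP alleles must be A/C/G/T; saw: ",
                               paste(unique(x[bad]), collapse = ", ")))
    x
  } else {
    suppressWarnings(v <- as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) abort(paste0("Non-numeric SSR allele(s): ",
                               paste(unique(x[bad]), collapse = ", ")))
    as.integer(round(v))
  }
}

check_range <- function(alleles, panel_row) {
  if (is.na(panel_row$range_min) || panel_row$system == "SNP") return(invisible())
  v <- suppressWarnings(as.numeric(alleles))
  out <- !is.na(v) & (v < panel_row$range_min | v > panel_row$range_max)
  if (any(out)) {
    warn(paste0("Locus ", panel_row$locus, ": ", sum(out),
                " allele(s) outside expected range [", panel_row$range_min,
                ", ", panel_row$range_max, "]; retained."))
  }
  invisible()
}

#' Write a genotype table to CSV
#'
#' Writes the two-column-per-nuclear-locus dialect read by
#' [read_genotype_csv()]; missing cells are left empty.
#'
#' @param gt A `vk_geno` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(gt, path) {
  panel <- gt_panel(gt)
  keep <- c("id", unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$system[i] == "cpSSR") panel$locus[i]
    else paste0(panel$locus[i], c("_1", "_2"))
  })))
  readr::write_csv(as_tibble(gt)[, keep], path, na = "")
  invisible(path)
}
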
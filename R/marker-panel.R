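#' Define a marker panel
#'
#' A marker panel describes the loci of a genotyping experiment: locus names,
#' marker system (nuclear microsatellite `"SSR"`, biallelic `"SNP"`, or
#' haploid chloroplast microsatellite `"cpSSR"`), the repeat-motif length in
#' bp for microsatellites, the panel category the locus belongs to
#' (`"cat1"` fingerprinting, `"cat2"` diversity/parentage, `"cat3"`
#' structure support, `"cat4"` chlorotype), and an optional expected
#' fragment-size range.
#'
#' @param locus Character vector of unique locus names.
#' @param system Marker system per locus: `"SSR"`, `"SNP"` or `"cpSSR"`.
#' @param motif_length Integer repeat length in bp (required for SSR/cpSSR,
#'   `NA` for SNP).
#' @param category Panel category `"cat1"`..`"cat4"`. `"cat4"` is reserved
#'   for cpSSR loci.
#' @param range_min,range_max Optional expected allele size range (bp).
#' @return A tibble of class `vk_panel`, one row per locus.
#' @examples
#' marker_panel(c("VVS2", "VVMD5"), "SSR", motif_length = 2, category = "cat1")
#' @export
marker_panel <- function(locus, system, motif_length = NA_integer_,
                         category = "cat1", range_min = NA_real_,
                         range_max = NA_real_) {
  panel <- tibble(
    locus = as.character(locus),
    system = as.character(system),
    motif_length = as.integer(motif_length),
    category = as.character(category),
    range_min = as.numeric(range_min),
    range_max = as.numeric(range_max)
  )
  validate_marker_panel(panel)
}

#' Read a marker panel definition file
#'
#' Expects a CSV with columns `locus`, `system`, `motif_length`, `category`
#' and optionally `range_min`, `range_max`.
#'
#' @param path Path to the CSV file.
#' @return A `vk_panel` tibble.
#' @export
read_marker_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"range_min" %in% names(df)) df$range_min <- NA_real_
  if (!"range_max" %in% names(df)) df$range_max <- NA_real_
  marker_panel(df$locus, df$system, df$motif_length, df$category,
               df$range_min, df$range_max)
}

validate_marker_panel <- function(panel) {
  if (!is.data.frame(panel)) abort("A marker panel must be a data frame.")
  need <- c("locus", "system", "category")
  if (!all(need %in% names(panel))) {
    abort(paste0("Marker panel must have columns: ", paste(need, collapse = ", "), "."))
  }
  if (!"motif_length" %in% names(panel)) panel$motif_length <- NA_integer_
  if (!"range_min" %in% names(panel)) panel$range_min <- NA_real_
  if (!"range_max" %in% names(panel)) panel$range_max <- NA_real_
  if (anyDuplicated(panel$locus)) {
    abort("Locus names must be unique within a panel.")
  }
  bad <- setdiff(unique(panel$system), c("SSR", "SNP", "cpSSR"))
  if (length(bad)) abort(paste0("Unknown marker system: ", paste(bad, collapse = ", ")))
  bad_cat <- setdiff(unique(panel$category), paste0("cat", 1:4))
  if (length(bad_cat)) abort(paste0("Unknown category: ", paste(bad_cat, collapse = ", ")))
  if (any(panel$category == "cat4" & panel$system != "cpSSR")) {
    abort("Category cat4 is reserved for cpSSR loci.")
  }
  ssr <- panel$system %in% c("SSR", "cpSSR")
  if (any(ssr & !is.na(panel$motif_length) & panel$motif_length < 1)) {
    abort("motif_length must be >= 1 bp.")
  }
  panel <- as_tibble(panel[, c("locus", "system", "motif_length", "category",
                               "range_min", "range_max")])
  class(panel) <- c("vk_panel", class(tibble()))
  panel
}

#' Select loci from a panel
#'
#' @param panel A `vk_panel`.
#' @param category Optional categories to keep (e.g. `c("cat1", "cat2")`).
#' @param system Optional systems to keep.
#' @return Character vector of locus names.
#' @export
panel_loci <- function(panel, category = NULL, system = NULL) {
  panel <- validate_marker_panel(panel)
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(category)) keep <- keep & panel$category %in% category
  if (!is.null(system)) keep <- keep & panel$system %in% system
  panel$locus[keep]
}

nuclear_loci <- function(panel) panel$locus[panel$system %in% c("SSR", "SNP")]
cp_loci <- function(panel) panel$locus[panel$system == "cpSSR"]
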
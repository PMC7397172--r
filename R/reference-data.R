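#' Published reference locus statistics for a Croatian grapevine panel
#'
#' Per-locus diversity and identity statistics, as printed for a
#' 127-accession Croatian grapevine germplasm panel: 36 SSR loci
#' (`"ssr36"`), and 45 biallelic SNP loci typed on the 124-accession
#' subset (`"snp45"`). The nine-locus international fingerprinting subset
#' (`"ssr9"`) comprises VVS2, VVMD5, VVMD7, VVMD25, VVMD27, VVMD28,
#' VVMD32, ssrVrZAG62 and ssrVrZAG79. Values are rounded to the precision
#' of the source tables (P(ID) to three decimals), so products over many
#' loci carry that rounding.
#'
#' These tables support panel-level arithmetic -- cumulative probability
#' of identity, panel summaries and SSR-vs-SNP equivalence -- without
#' access to the underlying genotypes.
#'
#' @param panel `"ssr36"`, `"ssr9"` or `"snp45"`.
#' @return Tibble with columns `locus`, `n`, `md`, `na`, `ne`, `nar`,
#'   `he`, `ho`, `f`, `hw`, `fnull`, `pic`, `pid_u`, `pid_sib` (plus
#'   `maf`/`maf_allele` for SNPs, `range_min`/`range_max` for SSRs).
#' @export
ref_locus_stats <- function(panel = c("ssr36", "ssr9", "snp45")) {
  panel <- match.arg(panel)
  file <- switch(panel,
                 ssr36 = "ssr_locus_stats_hr127.tsv",
                 ssr9 = "ssr_locus_stats_hr127.tsv",
                 snp45 = "snp_locus_stats_hr124.tsv")
  path <- system.file("extdata", file, package = "vinekin", mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (panel == "ssr9") df <- df[df$locus %in% ssr9_loci(), ]
  df
}

#' @rdname ref_locus_stats
#' @export
ssr9_loci <- function() {
  c("VVS2", "VVMD5", "VVMD7", "VVMD25", "VVMD27", "VVMD28", "VVMD32",
    "ssrVrZAG62", "ssrVrZAG79")
}
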
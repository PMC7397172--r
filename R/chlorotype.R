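#' Build or read a chlorotype lookup map
#'
#' A chlorotype map assigns a haplotype letter (A-H) to each combination of
#' fragment lengths at the chloroplast microsatellite loci. The chloroplast
#' is maternally inherited, so the letter travels from mother to offspring
#' unchanged.
#'
#' @param df Data frame with one column per cpSSR locus plus a
#'   `chlorotype` column of single letters A-H. Combinations must be
#'   unique.
#' @return A validated `vk_chloromap` tibble.
#' @export
chlorotype_map <- function(df) {
  df <- as_tibble(df)
  if (!"chlorotype" %in% names(df)) abort("Map needs a `chlorotype` column.")
  loci <- setdiff(names(df), "chlorotype")
  if (length(loci) == 0) abort("Map needs at least one cpSSR locus column.")
  if (!all(df$chlorotype %in% LETTERS[1:8])) {
    abort("Chlorotype letters must be A-H.")
  }
  combo <- do.call(paste, c(df[loci], sep = "|"))
  if (anyDuplicated(combo)) abort("Duplicate length combinations in the map.")
  attr(df, "cp_loci") <- loci
  class(df) <- c("vk_chloromap", class(df))
  df
}

#' @rdname chlorotype_map
#' @param path CSV file with the same columns.
#' @export
read_chlorotype_map <- function(path) {
  chlorotype_map(readr::read_csv(path, show_col_types = FALSE))
}

#' Assign chlorotypes from cpSSR fragment lengths
#'
#' Exact-match lookup of each accession's cpSSR length combination in the
#' map. Any missing cp locus, or a combination absent from the map, yields
#' `"n.d."` (not determined) -- maternity is never inferred through a
#' missing chlorotype.
#'
#' @param gt Genotype table containing the map's cpSSR locus columns.
#' @param map A [chlorotype_map()].
#' @return Tibble `id`, `chlorotype` (letter or `"n.d."`).
#' @export
assign_chlorotype <- function(gt, map) {
  loci <- attr(map, "cp_loci")
  missing_cols <- setdiff(loci, names(gt))
  if (length(missing_cols)) {
    abort(paste0("Table lacks cpSSR column(s): ", paste(missing_cols, collapse = ", ")))
  }
  key <- do.call(paste, c(map[loci], sep = "|"))
  obs <- do.call(paste, c(lapply(gt[loci], as.character), sep = "|"))
  has_na <- Reduce(`|`, lapply(gt[loci], is.na))
  hit <- match(obs, key)
  chl <- ifelse(has_na | is.na(hit), "n.d.", map$chlorotype[hit])
  tibble(id = gt$id, chlorotype = chl)
}

#' Chlorotype frequencies by region
#'
#' Counts and proportions of each chlorotype within each region;
#' undetermined (`"n.d."`) accessions are excluded from the denominators.
#' Accessions without a region are grouped under `"unknown"`.
#'
#' @param assignments Output of [assign_chlorotype()].
#' @param metadata Tibble with `id` and `region`.
#' @return Tibble `region`, `chlorotype`, `n`, `prop` (class
#'   `vk_chlorofreq`).
#' @export
chlorotype_frequencies <- function(assignments, metadata = NULL) {
  df <- assignments
  if (!is.null(metadata)) {
    df <- left_join(df, metadata[, c("id", "region")], by = "id")
  }
  if (!"region" %in% names(df)) df$region <- "all"
  df$region[is.na(df$region)] <- "unknown"
  out <- df |>
    filter(.data$chlorotype != "n.d.") |>
    dplyr::count(.data$region, .data$chlorotype, name = "n") |>
    group_by(.data$region) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
  class(out) <- c("vk_chlorofreq", class(out))
  out
}

#' @export
autoplot.vk_chlorofreq <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$region, y = .data$prop,
                               fill = .data$chlorotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "share of varieties", x = NULL, fill = "chlorotype") +
    ggplot2::theme_minimal()
}

#' Designate the maternal parent of accepted trios
#'
#' The chloroplast follows the seed parent, so inside a trio whose parents
#' carry different chlorotypes the mother is the parent matching the
#' offspring. Identical parental chlorotypes, or any member undetermined,
#' leave maternity `"undetermined"`; an offspring matching neither parent
#' is flagged `"conflict"` (impossible under strict maternal inheritance
#' -- it indicates a wrong trio or a cp scoring error).
#'
#' @param trios [assign_parentage()] result (rows with `type == "trio"`
#'   are considered).
#' @param assignments [assign_chlorotype()] result covering the ids.
#' @return `trios` with the `maternal` column filled in (`parent id`,
#'   `"undetermined"` or `"conflict"`).
#' @export
designate_mother <- function(trios, assignments) {
  chl <- setNames(assignments$chlorotype, assignments$id)
  get <- function(id) {
    v <- chl[id]
    ifelse(is.na(id) | is.na(v), "n.d.", v)
  }
  out <- trios
  for (i in seq_len(nrow(out))) {
    if (!identical(out$type[i], "trio")) next
    co <- get(out$offspring[i]); c1 <- get(out$parent1[i]); c2 <- get(out$parent2[i])
    out$maternal[i] <-
      if (co == "n.d." || c1 == "n.d." || c2 == "n.d.") "undetermined"
      else if (c1 == c2) "undetermined"
      else if (co == c1) out$parent1[i]
      else if (co == c2) out$parent2[i]
      else "conflict"
  }
  out
}
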
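#' Analysis of molecular variance (AMOVA) on a distance matrix
#'
#' Partitions squared pairwise distances into among- and within-group sums
#' of squares, estimates the variance components, and reports
#' `Phi_PT = sigma2_among / (sigma2_among + sigma2_within)` with a
#' permutation p-value (random relabelling of individuals, +1 correction).
#' Pairwise Phi between every group pair is computed by restricting the
#' matrix to the two groups.
#'
#' @param dm A `vk_dist` (complete) or a square distance matrix.
#' @param groups Named character vector or tibble (`id`, `group`) giving a
#'   group per accession; groups of size 1 are dropped with a warning.
#' @param n_perm Permutations (default 999).
#' @param seed Seed for the permutations.
#' @return A `vk_amova`: list with `components` (tibble), `phi_pt`,
#'   `p_value`, `pairwise` (tibble of group pairs with `phi` and `p`),
#'   `n_perm`, `seed`.
#' @export
amova <- function(dm, groups, n_perm = 999, seed = 1) {
  if (inherits(dm, "vk_dist")) {
    if (any(is.na(dm$d))) abort("Distance matrix incomplete; cannot run AMOVA.")
    d <- dm$d
  } else d <- as.matrix(dm)
  if (is.data.frame(groups)) groups <- setNames(as.character(groups$group), groups$id)
  ids <- rownames(d) %||% names(groups)
  g <- groups[ids]
  if (anyNA(g)) abort("Every accession in the matrix needs a group label.")
  sizes <- table(g)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warn(paste0("Dropping size-1 group(s): ", paste(drop, collapse = ", ")))
    keep <- !g %in% drop
    d <- d[keep, keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2) abort("Need >= 2 groups with >= 2 members.")
  set.seed(seed)
  obs <- amova_phi(d, g)
  perm_phi <- vapply(seq_len(n_perm), function(r) {
    amova_phi(d, sample(g))$phi
  }, 1)
  p <- (sum(perm_phi >= obs$phi) + 1) / (n_perm + 1)
  # pairwise Phi
  gl <- sort(unique(g))
  pw <- list()
  if (length(gl) > 2) {
    cmb <- combn(gl, 2)
    pw <- lapply(seq_len(ncol(cmb)), function(c2) {
      pick <- g %in% cmb[, c2]
      sub <- amova_phi(d[pick, pick], g[pick])
      pp <- vapply(seq_len(n_perm), function(r) {
        amova_phi(d[pick, pick], sample(g[pick]))$phi
      }, 1)
      tibble(group_a = cmb[1, c2], group_b = cmb[2, c2], phi = sub$phi,
             p = (sum(pp >= sub$phi) + 1) / (n_perm + 1))
    })
  }
  comp <- tibble(
    source = c("among groups", "within groups"),
    df = c(obs$df_a, obs$df_w),
    ss = c(obs$ssa, obs$ssw),
    ms = c(obs$ssa / obs$df_a, obs$ssw / obs$df_w),
    sigma2 = c(obs$s2a, obs$s2w)
  )
  structure(list(components = comp, phi_pt = obs$phi, p_value = p,
                 pairwise = if (length(pw)) bind_rows(pw) else NULL,
                 n_perm = n_perm, seed = seed,
                 groups = tibble(id = rownames(d), group = unname(g))),
            class = "vk_amova")
}

# Phi from squared distances (the squared-distance SS identity:
# SS of a group = sum of squared distances within / group size)
amova_phi <- function(d, g) {
  d2 <- d^2
  N <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / N
  gl <- unique(g)
  ssw <- 0
  for (gg in gl) {
    ix <- which(g == gg)
    sub <- d2[ix, ix, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(ix)
  }
  ssa <- sst - ssw
  df_a <- length(gl) - 1
  df_w <- N - length(gl)
  s2w <- ssw / df_w
  sizes <- table(g)
  n0 <- (N - sum(sizes^2) / N) / df_a
  s2a <- (ssa / df_a - s2w) / n0
  phi <- if (s2a + s2w <= 0) 0 else s2a / (s2a + s2w)
  list(phi = phi, ssa = ssa, ssw = ssw, df_a = df_a, df_w = df_w,
       s2a = s2a, s2w = s2w)
}

#' @export
print.vk_amova <- function(x, ...) {
  cat("# AMOVA (", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  print(x$components)
  cat("# Phi_PT = ", round(x$phi_pt, 4), ", p = ", format.pval(x$p_value), "\n", sep = "")
  if (!is.null(x$pairwise)) { cat("# pairwise:\n"); print(x$pairwise) }
  invisible(x)
}

#' @export
tidy.vk_amova <- function(x, ...) x$components

#' @export
glance.vk_amova <- function(x, ...) {
  tibble(phi_pt = x$phi_pt, p_value = x$p_value,
         n_groups = length(unique(x$groups$group)),
         n = nrow(x$groups), n_perm = x$n_perm)
}
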
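# Fixtures and independent oracles used across the suite.

toy_ssr_panel <- function(loci = c("L1", "L2"), motif = 2) {
  marker_panel(loci, "SSR", motif_length = motif, category = "cat1")
}

toy_table <- function(df, panel) genotype_table(tibble::tibble(!!!df), panel)

# random small diploid table over `n_alleles` equifrequent-ish alleles
random_table <- function(n_ind, n_loci, n_alleles = 5, seed,
                         missing_rate = 0, probs = NULL) {
  set.seed(seed)
  panel <- marker_panel(sprintf("R%02d", seq_len(n_loci)), "SSR",
                        motif_length = 2, category = "cat1")
  df <- tibble::tibble(id = sprintf("i%03d", seq_len(n_ind)))
  for (l in panel$locus) {
    sizes <- 100 + 2 * seq_len(n_alleles)
    a <- sample(sizes, n_ind, replace = TRUE, prob = probs)
    b <- sample(sizes, n_ind, replace = TRUE, prob = probs)
    drop <- runif(n_ind) < missing_rate
    a[drop] <- NA; b[drop] <- NA
    df[[paste0(l, "_1")]] <- pmin(a, b)
    df[[paste0(l, "_2")]] <- pmax(a, b)
  }
  genotype_table(df, panel)
}

# --- brute-force diversity oracle: explicit loops, no shared code ---------

oracle_locus_stats <- function(gt, locus) {
  a1 <- gt[[paste0(locus, "_1")]]; a2 <- gt[[paste0(locus, "_2")]]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  copies <- c(a1, a2)
  alleles <- sort(unique(copies))
  p <- vapply(alleles, function(x) sum(copies == x) / length(copies), 1)
  names(p) <- as.character(alleles)
  he <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i != j) he <- he + p[i] * p[j]
  }
  pic <- he
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) pic <- pic - 2 * p[i]^2 * p[j]^2
  }
  pid_u <- sum(p^4)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) pid_u <- pid_u + (2 * p[i] * p[j])^2
  }
  s2 <- sum(p^2); s4 <- sum(p^4)
  pid_sib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  list(he = unname(he), ho = mean(a1 != a2), ne = unname(1 / s2),
       na = length(alleles), pic = unname(pic), pid_u = unname(pid_u),
       pid_sib = unname(pid_sib), p = p)
}

# --- brute-force UPGMA oracle: recompute all average linkages each step ---

oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- c()
  labels <- rownames(d)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d - 1e-12) { best <- c(i, j); best_d <- dd }
    }
    heights <- c(heights, best_d / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# --- alignment oracle: exhaustive search over column permutations ---------

oracle_best_g <- function(qa, qb) {
  perms <- combinat_perms(ncol(qa))
  best <- -Inf
  for (p in perms) {
    g <- 1 - sqrt(sum((qa[, p] - qb)^2)) / sqrt(2 * nrow(qa))
    if (g > best) best <- g
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(k - 1)) for (pos in seq_len(k)) {
    out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  }
  out
}

# a small founder population shared by the parentage/kinship tests
parentage_founders <- function(seed = 9, n = 127, n_ssr = 20) {
  cfg <- sim_pop_config(n_pools = 1, pool_sizes = n, n_ssr = n_ssr,
                        n_snp = 0, n_cp = 4, seed = seed,
                        high_missing_locus = FALSE, missing_rate = 0.02)
  gen_population(cfg)
}
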
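#' Configuration for the synthetic germplasm generator
#'
#' Defaults emulate a Croatian-style grapevine germplasm panel: 127
#' diploid individuals, 36 SSR loci carrying 2-15 alleles with a mean
#' around nine, 45 biallelic SNP loci, a few percent missing data with one
#' badly amplifying SSR locus near 50\% missing, four cpSSR loci encoding
#' eight maternally inherited chlorotypes with C and D dominating, and an
#' F-model population structure (pool frequencies Dirichlet-dispersed
#' around ancestral frequencies with drift `drift`).
#'
#' @param n_pools Number of ancestral pools K.
#' @param pool_sizes Individuals per pool (recycled).
#' @param drift F-model drift per pool (recycled); 0.15 is moderate
#'   between-region divergence.
#' @param admixed_frac Fraction of individuals with Dirichlet-mixed
#'   ancestry instead of pure pool origin.
#' @param admix_alpha Dirichlet parameter of admixed ancestry vectors.
#' @param n_ssr,n_snp Locus counts.
#' @param allele_range,mean_alleles SSR allele count distribution:
#'   truncated discretized normal over `allele_range` centred to give the
#'   target mean.
#' @param missing_rate Per-locus missing-cell rate.
#' @param high_missing_locus Give one SSR locus ~50\% missing data?
#' @param null_locus Plant one SSR locus with a segregating null allele
#'   (frequency `null_freq`) that silently converts carriers to apparent
#'   homozygotes?
#' @param null_freq Null-allele frequency for that locus.
#' @param error_rate Per-genotype error rate (replacement by a random
#'   pool genotype).
#' @param n_cp cpSSR locus count.
#' @param seed Integer seed (mandatory: generators are pure functions of
#'   the configuration and seed).
#' @return A `vk_sim_pop_config` list.
#' @export
sim_pop_config <- function(n_pools = 1, pool_sizes = 127, drift = 0.15,
                           admixed_frac = 0, admix_alpha = 1,
                           n_ssr = 36, n_snp = 45,
                           allele_range = c(2, 15), mean_alleles = 9,
                           missing_rate = 0.02, high_missing_locus = TRUE,
                           null_locus = FALSE, null_freq = 0.25,
                           error_rate = 0, n_cp = 4, seed) {
  if (missing(seed)) abort("A seed is mandatory.")
  rates <- c(admixed_frac, missing_rate, error_rate, null_freq, drift)
  if (any(rates < 0 | rates > 1)) abort("All rates must be in [0, 1].")
  structure(list(n_pools = n_pools,
                 pool_sizes = rep_len(pool_sizes, n_pools),
                 drift = rep_len(drift, n_pools),
                 admixed_frac = admixed_frac, admix_alpha = admix_alpha,
                 n_ssr = n_ssr, n_snp = n_snp,
                 allele_range = allele_range, mean_alleles = mean_alleles,
                 missing_rate = missing_rate,
                 high_missing_locus = high_missing_locus,
                 null_locus = null_locus, null_freq = null_freq,
                 error_rate = error_rate, n_cp = n_cp,
                 seed = as.integer(seed)),
            class = "vk_sim_pop_config")
}

# default synthetic chlorotype map: 8 letters over 4 cpSSR loci, two
# length variants per locus
synthetic_chlorotype_map <- function(n_cp = 4) {
  base <- c(106, 91, 114, 99)[seq_len(n_cp)]
  combos <- expand.grid(rep(list(0:1), n_cp))[seq_len(8), , drop = FALSE]
  df <- as_tibble(setNames(
    lapply(seq_len(n_cp), function(j) base[j] + combos[[j]]),
    paste0("ccmp", seq_len(n_cp))))
  df$chlorotype <- LETTERS[1:8]
  chlorotype_map(df)
}

rdirichlet1 <- function(par) {
  g <- stats::rgamma(length(par), shape = par, rate = 1)
  g <- pmax(g, 1e-12)
  g / sum(g)
}

#' Generate a synthetic germplasm population with known truth
#'
#' Draws ancestral allele frequencies per locus from a flat Dirichlet
#' (SSR) or a uniform minor-allele frequency (SNP), disperses them into
#' pool frequencies under the F-model, and samples individuals in
#' Hardy-Weinberg proportions within pools -- admixed individuals draw
#' each allele copy from a pool chosen by their Dirichlet ancestry vector.
#' Missingness, a pathological high-missing locus, an optional null-allele
#' locus, genotyping errors and maternally transmitted cpSSR haplotypes
#' are layered on top. Everything is a pure function of `(cfg, seed)`.
#'
#' @param cfg A [sim_pop_config()].
#' @return List with `table` (a `vk_geno`), `truth` (list: `ancestry`
#'   tibble with pool of origin and true Q vector, `chlorotype`,
#'   `meta` with a region per pool, `pool_freqs`), and `map` (the
#'   chlorotype map used).
#' @export
gen_population <- function(cfg) {
  set.seed(cfg$seed)
  K <- cfg$n_pools
  n <- sum(cfg$pool_sizes)
  ids <- sprintf("acc%03d", seq_len(n))
  pool <- rep(seq_len(K), cfg$pool_sizes)

  # SSR allele-count distribution: discretized normal on the allowed range
  rng <- seq(cfg$allele_range[1], cfg$allele_range[2])
  if (cfg$mean_alleles < cfg$allele_range[1] || cfg$mean_alleles > cfg$allele_range[2]) {
    abort("mean_alleles outside allele_range: infeasible allele-count distribution.")
  }
  # discretized normal recentred so the truncated draw hits the target mean
  # (+0.5 compensates alleles too rare to be observed in the sample)
  draw_mean <- function(m) {
    w <- stats::dnorm(rng, m, 3); sum(rng * w) / sum(w)
  }
  target <- cfg$mean_alleles + 0.5
  m_star <- stats::uniroot(function(m) draw_mean(m) - target,
                           c(min(rng) - 6, max(rng) + 6))$root
  wt <- stats::dnorm(rng, m_star, 3)
  na_ssr <- sample(rng, cfg$n_ssr, replace = TRUE, prob = wt)

  motif <- sample(2:3, cfg$n_ssr, replace = TRUE)
  start <- sample(seq(100, 300), cfg$n_ssr, replace = TRUE)
  ssr_names <- sprintf("ssr%02d", seq_len(cfg$n_ssr))
  snp_names <- if (cfg$n_snp > 0) sprintf("snp%02d", seq_len(cfg$n_snp)) else character()
  cp_names <- if (cfg$n_cp > 0) paste0("ccmp", seq_len(cfg$n_cp)) else character()

  panel <- marker_panel(
    locus = c(ssr_names, snp_names, cp_names),
    system = c(rep("SSR", cfg$n_ssr), rep("SNP", cfg$n_snp), rep("cpSSR", cfg$n_cp)),
    motif_length = c(motif, rep(NA, cfg$n_snp), rep(1, cfg$n_cp)),
    category = c(rep(c("cat1", "cat2", "cat3"), length.out = cfg$n_ssr),
                 rep("cat3", cfg$n_snp), rep("cat4", cfg$n_cp)))

  # allele labels and ancestral/pool frequencies per nuclear locus
  loci <- c(ssr_names, snp_names)
  labels <- c(
    lapply(seq_len(cfg$n_ssr), function(j) start[j] + motif[j] * seq_len(na_ssr[j])),
    lapply(seq_len(cfg$n_snp), function(j) sort(sample(c("A", "C", "G", "T"), 2)))
  )
  names(labels) <- loci
  anc <- lapply(loci, function(l) {
    A <- length(labels[[l]])
    if (A == 2 && startsWith(l, "snp")) {
      maf <- runif(1, 0.05, 0.5)
      c(1 - maf, maf)
    } else rdirichlet1(rep(1, A))
  })
  # with a single pool the sample IS the population: no extra drift layer
  pool_freqs <- lapply(seq_len(K), function(k) {
    f <- cfg$drift[k]
    lapply(anc, function(pa) {
      if (K == 1 || f <= 0.001) pa else rdirichlet1(pa * (1 - f) / f)
    })
  })

  # ancestry vectors
  admixed <- runif(n) < cfg$admixed_frac & K > 1
  Qtrue <- matrix(0, n, K)
  Qtrue[cbind(seq_len(n), pool)] <- 1
  for (i in which(admixed)) Qtrue[i, ] <- rdirichlet1(rep(cfg$admix_alpha, K))

  draw_copy <- function(l_idx, i) {
    k <- if (K == 1) 1 else sample.int(K, 1, prob = Qtrue[i, ])
    p <- pool_freqs[[k]][[l_idx]]
    sample.int(length(p), 1, prob = p)
  }

  df <- tibble(id = ids)
  for (j in seq_along(loci)) {
    l <- loci[j]
    lab <- labels[[l]]
    # vectorised HW draws per pool; admixed individuals drawn copy-wise
    a1 <- integer(n); a2 <- integer(n)
    for (k in seq_len(K)) {
      ix <- which(pool == k & !admixed)
      p <- pool_freqs[[k]][[j]]
      a1[ix] <- sample.int(length(p), length(ix), replace = TRUE, prob = p)
      a2[ix] <- sample.int(length(p), length(ix), replace = TRUE, prob = p)
    }
    for (i in which(admixed)) { a1[i] <- draw_copy(j, i); a2[i] <- draw_copy(j, i) }
    # genotyping error: replace with a draw from the overall pool
    if (cfg$error_rate > 0) {
      pbar <- Reduce(`+`, lapply(seq_len(K), function(k) pool_freqs[[k]][[j]])) / K
      err <- runif(n) < cfg$error_rate
      a1[err] <- sample.int(length(pbar), sum(err), replace = TRUE, prob = pbar)
      a2[err] <- sample.int(length(pbar), sum(err), replace = TRUE, prob = pbar)
    }
    val1 <- lab[a1]; val2 <- lab[a2]
    if (is.numeric(lab)) {
      df[[paste0(l, "_1")]] <- as.integer(pmin(val1, val2))
      df[[paste0(l, "_2")]] <- as.integer(pmax(val1, val2))
    } else {
      df[[paste0(l, "_1")]] <- pmin(val1, val2)
      df[[paste0(l, "_2")]] <- pmax(val1, val2)
    }
  }

  # null-allele locus: carriers look homozygous, null homozygotes drop out
  null_info <- NULL
  if (cfg$null_locus) {
    l <- ssr_names[2]
    null_size <- max(labels[[l]]) + motif[2]
    carrier1 <- runif(n) < cfg$null_freq
    carrier2 <- runif(n) < cfg$null_freq
    c1 <- paste0(l, "_1"); c2 <- paste0(l, "_2")
    both <- carrier1 & carrier2
    df[[c1]][both] <- NA_integer_; df[[c2]][both] <- NA_integer_
    one <- xor(carrier1, carrier2)
    # the visible allele masquerades as a homozygote
    keepv <- ifelse(carrier1[one], df[[c2]][one], df[[c1]][one])
    df[[c1]][one] <- keepv; df[[c2]][one] <- keepv
    null_info <- tibble(locus = l, null_freq = cfg$null_freq,
                        null_size = null_size)
  }

  # missingness: uniform per locus, one pathological SSR locus near 50%
  rates <- setNames(rep(cfg$missing_rate, length(loci)), loci)
  if (cfg$high_missing_locus && cfg$n_ssr > 0) rates[ssr_names[1]] <- 0.5
  for (l in loci) {
    drop <- runif(n) < rates[l]
    if (any(drop)) {
      df[[paste0(l, "_1")]][drop] <- NA
      df[[paste0(l, "_2")]][drop] <- NA
    }
  }

  # cpSSR haplotypes: letters weighted like a coastal-inland germplasm
  map <- if (cfg$n_cp > 0) synthetic_chlorotype_map(cfg$n_cp) else NULL
  truth_chl <- NULL
  if (cfg$n_cp > 0) {
    wts <- c(A = 0.12, B = 0.02, C = 0.47, D = 0.30, E = 0.02, F = 0.03,
             G = 0.0, H = 0.04)
    letter <- sample(LETTERS[1:8], n, replace = TRUE, prob = wts[LETTERS[1:8]])
    rows <- match(letter, map$chlorotype)
    for (l in cp_names) df[[l]] <- map[[l]][rows]
    truth_chl <- tibble(id = ids, chlorotype = letter)
  }

  gt <- genotype_table(df, panel)
  ancestry <- bind_cols(tibble(id = ids, pool = pool, admixed = admixed),
                        as_tibble(setNames(as.data.frame(Qtrue),
                                           paste0("Q", seq_len(K)))))
  truth <- list(ancestry = ancestry,
                chlorotype = truth_chl,
                meta = tibble(id = ids, region = paste0("region", pool)),
                pool_freqs = pool_freqs, labels = labels,
                null_locus = null_info)
  list(table = gt, truth = truth, map = map)
}

#' Generate pedigree trios from founder genotypes
#'
#' Each offspring draws one allele per parent per nuclear locus (a missing
#' parental genotype transmits a random allele from the founder pool),
#' inherits its mother's cpSSR haplotype unchanged, and is typed with the
#' requested error rate (per-genotype replacement by a founder-frequency
#' Hardy-Weinberg draw).
#'
#' @param founders A `vk_geno` of founder genotypes.
#' @param n_trios Number of offspring.
#' @param selfing_rate Probability that father == mother.
#' @param error_rate Per-genotype error rate on the offspring.
#' @param seed Integer seed.
#' @param prefix Offspring id prefix.
#' @return List with `table` (founders plus offspring) and `truth`
#'   (tibble `offspring`, `mother`, `father`).
#' @export
gen_pedigree <- function(founders, n_trios, selfing_rate = 0,
                         error_rate = 0, seed, prefix = "off") {
  if (missing(seed)) abort("A seed is mandatory.")
  if (nrow(founders) < 2) abort("Need at least two founders.")
  set.seed(seed)
  panel <- gt_panel(founders)
  loci <- nuclear_loci(panel)
  cps <- cp_loci(panel)
  freqs <- allele_frequencies(founders, loci)
  n <- nrow(founders)
  mo <- sample.int(n, n_trios, replace = TRUE)
  fa <- ifelse(runif(n_trios) < selfing_rate, mo,
               sample.int(n, n_trios, replace = TRUE))
  ids <- sprintf("%s%03d", prefix, seq_len(n_trios))
  df <- tibble(id = ids)
  for (l in loci) {
    fl <- freqs[freqs$locus == l, ]
    pool_draw <- function(m) sample(fl$allele, m, replace = TRUE, prob = fl$freq)
    g1 <- as.character(founders[[paste0(l, "_1")]])
    g2 <- as.character(founders[[paste0(l, "_2")]])
    transmit <- function(pidx) {
      out <- ifelse(runif(n_trios) < 0.5, g1[pidx], g2[pidx])
      miss <- is.na(out)
      out[miss] <- pool_draw(sum(miss))
      out
    }
    a <- transmit(mo); b <- transmit(fa)
    if (error_rate > 0) {
      err <- runif(n_trios) < error_rate
      a[err] <- pool_draw(sum(err)); b[err] <- pool_draw(sum(err))
    }
    numeric_locus <- !is.character(founders[[paste0(l, "_1")]])
    if (numeric_locus) {
      av <- as.integer(a); bv <- as.integer(b)
      df[[paste0(l, "_1")]] <- pmin(av, bv)
      df[[paste0(l, "_2")]] <- pmax(av, bv)
    } else {
      df[[paste0(l, "_1")]] <- pmin(a, b)
      df[[paste0(l, "_2")]] <- pmax(a, b)
    }
  }
  for (l in cps) df[[l]] <- founders[[l]][mo]
  off <- genotype_table(df, panel)
  combined <- genotype_table(bind_rows(as_tibble(founders)[, names(as_tibble(off))],
                                       as_tibble(off)), panel)
  list(table = combined,
       offspring = off,
       truth = tibble(offspring = ids, mother = founders$id[mo],
                      father = founders$id[fa]))
}

#' Plant clone groups in a genotype table
#'
#' Copies chosen accessions and perturbs at most `max_mutations` allele
#' copies by one repeat unit (somatic mutation / scoring slip), recording
#' the planted groups as truth for duplicate-detection checks.
#'
#' @param gt A `vk_geno`.
#' @param n_groups Number of accessions to clone.
#' @param max_mutations Maximum mutated allele copies per clone (default
#'   2, the usual duplicate tolerance).
#' @param n_mutations Exact mutation count per clone (overrides the random
#'   0..`max_mutations` draw; use 3 for a negative control).
#' @param seed Integer seed.
#' @return List with `table` (original plus clones) and `truth` (tibble
#'   `id`, `clone_of`, `n_mutations`).
#' @export
gen_clones <- function(gt, n_groups, max_mutations = 2, n_mutations = NULL,
                       seed) {
  if (missing(seed)) abort("A seed is mandatory.")
  set.seed(seed)
  panel <- gt_panel(gt)
  ssr <- panel$locus[panel$system == "SSR"]
  picks <- sample(gt$id, n_groups)
  clones <- list(); truths <- list()
  for (g in seq_along(picks)) {
    src <- as_tibble(gt)[gt$id == picks[g], ]
    clone <- src
    clone$id <- paste0(picks[g], "_cl1")
    nm <- if (is.null(n_mutations)) sample(0:max_mutations, 1) else n_mutations
    typed <- ssr[vapply(ssr, function(l) !is.na(src[[paste0(l, "_1")]]), TRUE)]
    mut_loci <- sample(typed, nm, replace = FALSE)
    for (l in mut_loci) {
      side <- sample(1:2, 1)
      col <- paste0(l, "_", side)
      step <- panel$motif_length[panel$locus == l] * sample(c(-1, 1), 1)
      clone[[col]] <- clone[[col]] + step
      # keep the stored pair sorted
      c1 <- paste0(l, "_1"); c2 <- paste0(l, "_2")
      lo <- pmin(clone[[c1]], clone[[c2]]); hi <- pmax(clone[[c1]], clone[[c2]])
      clone[[c1]] <- lo; clone[[c2]] <- hi
    }
    clones[[g]] <- clone
    truths[[g]] <- tibble(id = clone$id, clone_of = picks[g],
                          n_mutations = nm)
  }
  tab <- genotype_table(bind_rows(as_tibble(gt), bind_rows(clones)), panel)
  list(table = tab, truth = bind_rows(truths))
}
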
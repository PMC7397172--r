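#' Single-locus parentage likelihood ratio
#'
#' Likelihood ratio at one locus for the hypothesis that the candidate(s)
#' are the offspring's parent (pair) versus the offspring being a random
#' draw from the allele pool. The genotyping-error model replaces each
#' observed genotype, independently with probability `eps`, by a random
#' Hardy-Weinberg genotype; an allele incompatibility therefore contributes
#' a finite negative log-ratio instead of an outright exclusion when
#' `eps > 0`. With a single candidate the other parent is integrated over
#' the allele frequencies.
#'
#' @param g_off,g_par1,g_par2 Length-2 allele vectors (character or
#'   numeric); `g_par2 = NULL` for the single-parent (duo) ratio.
#' @param freqs Named numeric vector of allele frequencies at the locus
#'   (an optional `gene_count` attribute sets the floor frequency
#'   `1/(gene_count+1)` used for alleles missing from the table).
#' @param eps Per-genotype error rate in \[0, 0.5) (default 0.01).
#' @return The likelihood ratio (a positive number; 0 only when `eps = 0`
#'   and the candidates are incompatible).
#' @export
transition_probability <- function(g_off, g_par1, g_par2 = NULL, freqs,
                                   eps = 0.01) {
  if (eps < 0 || eps >= 0.5) abort("eps must be in [0, 0.5).")
  p <- normalize_freqs(freqs, c(g_off, g_par1, g_par2))
  a <- as.character(g_off[1]); b <- as.character(g_off[2])
  pg <- hw_prob(a, b, p)
  t1 <- trans_vec(g_par1, p)
  T1a <- trans_prob(a, b, t1, p)
  if (is.null(g_par2)) {
    r <- ((1 - eps)^2 * T1a + (1 - (1 - eps)^2) * pg) / pg
  } else {
    t2 <- trans_vec(g_par2, p)
    T1b <- trans_prob(a, b, t2, p)
    T2 <- if (a == b) t1[a] * t2[a] else t1[a] * t2[b] + t1[b] * t2[a]
    r <- ((1 - eps)^3 * T2 + (1 - eps)^2 * eps * (T1a + T1b) +
            ((1 - eps) * eps^2 + eps) * pg) / pg
  }
  unname(r)
}

normalize_freqs <- function(freqs, seen) {
  p <- freqs
  seen <- as.character(stats::na.omit(seen))
  absent <- setdiff(seen, names(p))
  if (length(absent)) {
    gc <- attr(freqs, "gene_count") %||% (2 / min(p))
    floor_f <- 1 / (gc + 1)
    warn(paste0("Allele(s) absent from the frequency table (",
                paste(absent, collapse = ", "), "); added at floor frequency ",
                signif(floor_f, 3), "."))
    p <- c(p, setNames(rep(floor_f, length(absent)), absent))
  }
  p / sum(p)
}

# transmission vector over alleles for a parent genotype
trans_vec <- function(g, p) {
  t <- setNames(rep(0, length(p)), names(p))
  g <- as.character(g)
  t[g[1]] <- t[g[1]] + 0.5
  t[g[2]] <- t[g[2]] + 0.5
  t
}

trans_prob <- function(a, b, t, p) {
  if (a == b) t[[a]] * p[[a]] else t[[a]] * p[[b]] + t[[b]] * p[[a]]
}

hw_prob <- function(a, b, p) {
  if (a == b) p[[a]]^2 else 2 * p[[a]] * p[[b]]
}

#' Multilocus parentage LOD for one offspring/candidate combination
#'
#' Sums the log likelihood ratio of [transition_probability()] over the
#' loci typed in the offspring and all candidates involved.
#'
#' @param gt Genotype table containing all individuals.
#' @param offspring,parent1,parent2 Accession ids (`parent2 = NULL` for a
#'   duo).
#' @param loci Loci to use; default all nuclear loci.
#' @param eps Per-genotype error rate.
#' @param freqs Optional precomputed [allele_frequencies()] table; default
#'   computed from `gt` over `loci`.
#' @return One-row tibble: ids, `loci_compared`, `mismatches` (loci whose
#'   error-free transmission probability is zero), `lod`.
#' @export
lod_parentage <- function(gt, offspring, parent1, parent2 = NULL,
                          loci = NULL, eps = 0.01, freqs = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  freqs <- freqs %||% allele_frequencies(gt, loci)
  lod <- 0; lc <- 0L; mm <- 0L
  for (loc in loci) {
    go <- genotype_at(gt, offspring, loc)
    g1 <- genotype_at(gt, parent1, loc)
    g2 <- if (is.null(parent2)) NULL else genotype_at(gt, parent2, loc)
    if (anyNA(go) || anyNA(g1) || (!is.null(parent2) && anyNA(g2))) next
    p <- freq_vector(freqs, loc)
    lc <- lc + 1L
    r0 <- transition_probability(go, g1, g2, p, eps = 0)
    if (r0 == 0) mm <- mm + 1L
    lod <- lod + log(transition_probability(go, g1, g2, p, eps = eps))
  }
  tibble(offspring = offspring, parent1 = parent1,
         parent2 = parent2 %||% NA_character_,
         loci_compared = lc, mismatches = mm, lod = lod)
}

genotype_at <- function(gt, id, locus) {
  i <- match(id, gt$id)
  if (is.na(i)) abort(paste0("Unknown id: ", id))
  c(gt[[paste0(locus, "_1")]][i], gt[[paste0(locus, "_2")]][i])
}

freq_vector <- function(freqs, locus) {
  fl <- freqs[freqs$locus == locus, ]
  structure(setNames(fl$freq, fl$allele), gene_count = 2 * fl$n_typed[1])
}

#' Configuration of the parentage simulation
#'
#' Defaults follow the usual field calibration: one million simulated
#' offspring, 1\% of candidate parents assumed sampled, self-fertilization
#' possible, relatives present among the candidates (relatedness enters
#' through the candidate genotypes supplied), a 1\% genotyping error rate,
#' and strict/relaxed confidence levels of 95\% and 80\%.
#'
#' @param n_offspring Number of simulated offspring.
#' @param prop_sampled Probability that a true parent is in the candidate
#'   set.
#' @param selfing_allowed May the two parents coincide?
#' @param relatives_present Documentation flag: candidates are used as
#'   given, including any relatives among them.
#' @param error_rate Per-genotype error rate applied to simulated
#'   offspring.
#' @param typed_rate Probability a simulated offspring is typed at a locus.
#' @param confidence Named vector of confidence levels.
#' @param max_mismatch_frac Mismatch budget applied to simulated
#'   assignments, mirroring the rule used on real data.
#' @param top_m Trio search breadth: pairs are formed among the `top_m`
#'   candidates by single-parent LOD (plus the true pair).
#' @return A `vk_sim_config` list.
#' @export
parentage_sim_config <- function(n_offspring = 1e6, prop_sampled = 0.01,
                                 selfing_allowed = TRUE,
                                 relatives_present = TRUE,
                                 error_rate = 0.01, typed_rate = 0.98,
                                 confidence = c(strict95 = 0.95, relaxed80 = 0.80),
                                 max_mismatch_frac = 0.05, top_m = 8) {
  rates <- c(prop_sampled, error_rate, typed_rate, confidence, max_mismatch_frac)
  if (any(rates < 0 | rates > 1)) abort("All rates must be in [0, 1].")
  structure(list(n_offspring = as.integer(n_offspring),
                 prop_sampled = prop_sampled,
                 selfing_allowed = selfing_allowed,
                 relatives_present = relatives_present,
                 error_rate = error_rate, typed_rate = typed_rate,
                 confidence = confidence,
                 max_mismatch_frac = max_mismatch_frac,
                 top_m = as.integer(top_m)),
            class = "vk_sim_config")
}

# internal: indexed genotypes + frequency vectors for fast likelihoods
pk_data <- function(gt, loci, freqs = NULL) {
  enc <- encode_alleles(gt, loci)
  freqs <- freqs %||% allele_frequencies(gt, loci)
  p <- lapply(seq_along(loci), function(j) {
    fl <- freqs[freqs$locus == loci[j], ]
    v <- setNames(fl$freq, fl$allele)[enc$alleles[[loci[j]]]]
    v[is.na(v)] <- 1 / (2 * fl$n_typed[1] + 1)
    unname(v / sum(v))
  })
  # per-locus transmission-probability matrix: candidates x alleles
  list(enc = enc, p = p, loci = loci, ids = gt$id)
}

# transmission matrix for locus j: n x A, NA rows for untyped individuals
trans_matrix <- function(pk, j) {
  A <- pk$enc$n_alleles[j]
  i1 <- pk$enc$geno[, 2 * j - 1]; i2 <- pk$enc$geno[, 2 * j]
  n <- length(i1)
  M <- matrix(0, n, A)
  typed <- i1 > 0
  M[cbind(which(typed), i1[typed])] <- M[cbind(which(typed), i1[typed])] + 0.5
  M[cbind(which(typed), i2[typed])] <- M[cbind(which(typed), i2[typed])] + 0.5
  M[!typed, ] <- NA_real_
  M
}

#' Critical LOD thresholds by offspring simulation
#'
#' Simulates offspring whose parents are drawn from the candidate set with
#' probability `prop_sampled` (otherwise from unsampled Hardy-Weinberg
#' genotypes), types them with the configured missingness and error rate,
#' runs the same machinery used for real assignments -- trios: best pair
#' among the `top_m` single-parent candidates plus the true pair, subject
#' to the mismatch budget; duos: best single candidate -- and finds, for
#' each confidence level, the smallest LOD threshold at which the
#' proportion of correct assignments among those at or above it reaches
#' the level.
#'
#' To keep the estimate stable at modest simulation sizes the three
#' parentage cases (both true parents sampled / one / neither) are
#' simulated as equal-size strata and re-weighted by their true
#' probabilities (`prop_sampled^2` etc.) when the reliability curve is
#' accumulated; the estimand is unchanged, only its Monte Carlo variance.
#'
#' @param gt Genotype table of the candidate parents (and only them).
#' @param loci Loci to simulate over.
#' @param cfg A [parentage_sim_config()].
#' @param seed Integer seed.
#' @param freqs Optional precomputed allele frequencies.
#' @return A `vk_lodsim`: tibble `analysis` (trio/duo), `level`,
#'   `critical_lod`, `assignment_rate`, `reliability`, plus the simulated
#'   LOD distributions as attributes.
#' @export
simulate_critical_lod <- function(gt, loci = NULL, cfg = parentage_sim_config(),
                                  seed = 1, freqs = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  if (nrow(gt) < 10) warn("Fewer than 10 candidates: thresholds will be wide.")
  pk <- pk_data(gt, loci, freqs)
  set.seed(seed)
  nC <- nrow(gt)
  L <- length(loci)
  eps <- cfg$error_rate
  # --- stratified true parents: both sampled / one / neither ---
  ps <- cfg$prop_sampled
  case_prob <- c(both = ps^2, one = 2 * ps * (1 - ps), none = (1 - ps)^2)
  live <- case_prob > 0
  n_per <- round(cfg$n_offspring * ifelse(live, 1 / sum(live), 0))
  nO <- sum(n_per)
  stratum <- rep(names(case_prob), n_per)
  weight <- unname((case_prob / n_per)[stratum])
  sampledA <- stratum %in% c("both", "one")
  sampledB <- stratum == "both"
  idxA <- ifelse(sampledA, sample.int(nC, nO, replace = TRUE), NA_integer_)
  idxB <- ifelse(sampledB, sample.int(nC, nO, replace = TRUE), NA_integer_)
  if (!cfg$selfing_allowed) {
    clash <- !is.na(idxA) & !is.na(idxB) & idxA == idxB
    while (any(clash)) {
      idxB[clash] <- sample.int(nC, sum(clash), replace = TRUE)
      clash <- !is.na(idxA) & !is.na(idxB) & idxA == idxB
    }
  }
  # --- simulate offspring genotypes locus by locus ---
  off1 <- matrix(0L, nO, L); off2 <- matrix(0L, nO, L)
  for (j in seq_len(L)) {
    A <- pk$enc$n_alleles[j]; p <- pk$p[[j]]
    draw_pop <- function(n) sample.int(A, n, replace = TRUE, prob = p)
    transmit <- function(idx) {
      safe <- ifelse(is.na(idx), 1L, idx)
      g1 <- pk$enc$geno[safe, 2 * j - 1]; g2 <- pk$enc$geno[safe, 2 * j]
      out <- ifelse(runif(length(idx)) < 0.5, g1, g2)
      untyped <- !is.na(idx) & g1 == 0L   # untyped candidate: draw from pool
      out[untyped] <- draw_pop(sum(untyped))
      unsampled <- is.na(idx)
      out[unsampled] <- draw_pop(sum(unsampled))
      out
    }
    a <- transmit(idxA); b <- transmit(idxB)
    err <- runif(nO) < eps
    if (any(err)) { a[err] <- draw_pop(sum(err)); b[err] <- draw_pop(sum(err)) }
    untyped_off <- runif(nO) >= cfg$typed_rate
    a[untyped_off] <- 0L; b[untyped_off] <- 0L
    off1[, j] <- pmin(a, b); off2[, j] <- pmax(a, b)
  }
  scores <- parentage_scores(pk, off1, off2, eps, cfg$top_m,
                             true_a = idxA, true_b = idxB)
  # mismatch budget is panel-based: "one locus in twenty" on a 20-locus panel
  budget <- floor(cfg$max_mismatch_frac * L)
  duo_pass <- !is.na(scores$duo_best) &
    scores$single_mm[cbind(seq_len(nO), pmax(scores$duo_best, 1L))] <= budget
  trio_pass <- !is.na(scores$trio_lod) & scores$trio_mm <= budget
  duo_correct <- !is.na(scores$duo_best) &
    ((sampledA & scores$duo_best == idxA) | (sampledB & scores$duo_best == idxB))
  trio_correct <- !is.na(scores$trio_best_a) & sampledA & sampledB &
    ((scores$trio_best_a == idxA & scores$trio_best_b == idxB) |
     (scores$trio_best_a == idxB & scores$trio_best_b == idxA))
  rows <- list()
  for (lv in names(cfg$confidence)) {
    level <- cfg$confidence[[lv]]
    rows[[length(rows) + 1]] <- bind_rows(
      critical_from_sim("trio", lv, level, scores$trio_lod[trio_pass],
                        trio_correct[trio_pass], weight[trio_pass],
                        total_w = sum(weight)),
      critical_from_sim("duo", lv, level, scores$duo_lod[duo_pass],
                        duo_correct[duo_pass], weight[duo_pass],
                        total_w = sum(weight)))
  }
  out <- bind_rows(rows)
  structure(out, class = c("vk_lodsim", class(out)),
            trio_lod = scores$trio_lod, duo_lod = scores$duo_lod,
            trio_correct = trio_correct, duo_correct = duo_correct,
            trio_pass = trio_pass, duo_pass = duo_pass,
            weight = weight, stratum = stratum, cfg = cfg, seed = seed)
}

critical_from_sim <- function(analysis, level_name, level, lod, correct,
                              weight, total_w) {
  ok <- !is.na(lod)
  lod <- lod[ok]; correct <- correct[ok]; weight <- weight[ok]
  if (!length(lod)) {
    warn(paste0("No passing assignments in the ", analysis, " simulation."))
    return(tibble(analysis = analysis, level = level_name,
                  critical_lod = Inf, assignment_rate = 0,
                  reliability = NA_real_))
  }
  ord <- order(lod, decreasing = TRUE)
  rel <- cumsum((weight * correct)[ord]) / cumsum(weight[ord])
  hit <- which(rel >= level)
  if (!length(hit)) {
    warn(paste0("No threshold reaches ", level * 100, "% reliability (", analysis, ")."))
    crit <- max(lod) + 1
    rate <- 0; achieved <- NA_real_
  } else {
    m <- max(hit)
    if (m == length(ord)) {
      # reliability never dips below the level: no simulated spurious
      # assignment survived the mismatch rule, so the boundary lies below
      # the weakest simulated assignment. Fall back to the evidence floor
      # LOD = 0 (assign only when the parentage hypothesis is favored).
      crit <- 0
    } else {
      crit <- lod[ord][m]
    }
    rate <- cumsum(weight[ord])[m] / total_w
    achieved <- rel[m]
  }
  tibble(analysis = analysis, level = level_name, critical_lod = crit,
         assignment_rate = rate, reliability = achieved)
}

# Vectorised LOD machinery shared by simulation and assignment.
# off1/off2: nO x L allele-index matrices (0 = untyped).
# Returns single-parent LOD matrix statistics and best-pair trio results.
# The trio search evaluates pairs among the top_m candidates by single LOD
# (plus, in simulation, the true pair) unless full_pairs forces all pairs.
parentage_scores <- function(pk, off1, off2, eps, top_m,
                             true_a = NULL, true_b = NULL,
                             exclude_self = NULL, full_pairs = FALSE) {
  nO <- nrow(off1); L <- ncol(off1); nC <- length(pk$ids)
  one_m_e2 <- 1 - (1 - eps)^2
  single_lod <- matrix(0, nO, nC)
  single_mm <- matrix(0L, nO, nC)
  single_n <- matrix(0L, nO, nC)
  TMs <- lapply(seq_len(L), function(j) trans_matrix(pk, j))
  pgs <- vector("list", L)
  for (j in seq_len(L)) {
    p <- pk$p[[j]]
    a <- off1[, j]; b <- off2[, j]
    typed_o <- a > 0L
    pg <- rep(NA_real_, nO)
    het <- typed_o & a != b
    hom <- typed_o & a == b
    pg[het] <- 2 * p[a[het]] * p[b[het]]
    pg[hom] <- p[a[hom]]^2
    pgs[[j]] <- pg
    TM <- TMs[[j]]
    for (cc in seq_len(nC)) {
      tv <- TM[cc, ]
      if (is.na(tv[1])) next
      T1 <- rep(NA_real_, nO)
      T1[het] <- tv[a[het]] * p[b[het]] + tv[b[het]] * p[a[het]]
      T1[hom] <- tv[a[hom]] * p[a[hom]]
      use <- typed_o
      ratio <- ((1 - eps)^2 * T1[use] + one_m_e2 * pg[use]) / pg[use]
      single_lod[use, cc] <- single_lod[use, cc] + log(ratio)
      single_n[use, cc] <- single_n[use, cc] + 1L
      single_mm[use, cc] <- single_mm[use, cc] + (T1[use] == 0)
    }
  }
  if (!is.null(exclude_self)) {
    for (o in seq_len(nO)) {
      if (!is.na(exclude_self[o])) single_lod[o, exclude_self[o]] <- -Inf
    }
  }
  duo_best <- max.col(single_lod, ties.method = "first")
  duo_lod <- single_lod[cbind(seq_len(nO), duo_best)]
  duo_best[!is.finite(duo_lod)] <- NA_integer_

  # --- trio: candidate pairs among top_m single candidates (+ true pair) ---
  if (full_pairs) {
    m <- nC
    top_idx <- matrix(rep(seq_len(nC), each = nO), nO, nC)
  } else {
    m <- min(top_m, nC)
    top_idx <- matrix(0L, nO, m)
    for (o in seq_len(nO)) {
      top_idx[o, ] <- order(single_lod[o, ], decreasing = TRUE)[seq_len(m)]
    }
  }
  slots <- top_idx
  if (!is.null(true_a)) slots <- cbind(slots, ifelse(is.na(true_a), top_idx[, 1], true_a))
  if (!is.null(true_b)) slots <- cbind(slots, ifelse(is.na(true_b), top_idx[, 1], true_b))
  S <- ncol(slots)
  pair_idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  pair_idx <- rbind(pair_idx, cbind(seq_len(S), seq_len(S)))  # selfing pairs
  trio_lod <- rep(-Inf, nO)
  trio_a <- trio_b <- rep(NA_integer_, nO)
  trio_mm <- trio_n <- rep(NA_integer_, nO)
  # safe indices for matrix lookups: untyped (0) mapped to 1, masked below
  for (pp in seq_len(nrow(pair_idx))) {
    c1 <- slots[, pair_idx[pp, 1]]; c2 <- slots[, pair_idx[pp, 2]]
    lodv <- rep(0, nO); mmv <- rep(0L, nO); nv <- rep(0L, nO)
    for (j in seq_len(L)) {
      p <- pk$p[[j]]; TM <- TMs[[j]]; pg <- pgs[[j]]
      a <- off1[, j]; b <- off2[, j]
      typed_o <- a > 0L
      aa <- pmax(a, 1L); bb <- pmax(b, 1L)
      t1a <- TM[cbind(c1, aa)]; t1b <- TM[cbind(c1, bb)]
      t2a <- TM[cbind(c2, aa)]; t2b <- TM[cbind(c2, bb)]
      het <- aa != bb
      T1c1 <- ifelse(het, t1a * p[bb] + t1b * p[aa], t1a * p[aa])
      T1c2 <- ifelse(het, t2a * p[bb] + t2b * p[aa], t2a * p[aa])
      T2 <- ifelse(het, t1a * t2b + t1b * t2a, t1a * t2a)
      use <- typed_o & !is.na(T2)
      ratio <- ((1 - eps)^3 * T2[use] +
                  (1 - eps)^2 * eps * (T1c1[use] + T1c2[use]) +
                  ((1 - eps) * eps^2 + eps) * pg[use]) / pg[use]
      lodv[use] <- lodv[use] + log(ratio)
      nv[use] <- nv[use] + 1L
      mmv[use] <- mmv[use] + (T2[use] == 0)
    }
    if (!is.null(exclude_self)) {
      lodv[!is.na(exclude_self) & (c1 == exclude_self | c2 == exclude_self)] <- -Inf
    }
    better <- lodv > trio_lod & nv > 0L
    trio_lod[better] <- lodv[better]
    trio_a[better] <- pmin(c1, c2)[better]
    trio_b[better] <- pmax(c1, c2)[better]
    trio_mm[better] <- mmv[better]
    trio_n[better] <- nv[better]
  }
  trio_lod[!is.finite(trio_lod)] <- NA_real_
  list(single_lod = single_lod, single_mm = single_mm, single_n = single_n,
       duo_best = duo_best, duo_lod = duo_lod,
       trio_best_a = trio_a, trio_best_b = trio_b,
       trio_lod = trio_lod, trio_mm = trio_mm, trio_n = trio_n)
}

#' Assign parentage to offspring
#'
#' Runs the parent-pair (gender unknown) analysis first: for every
#' offspring the best-LOD candidate pair is accepted as a trio when its
#' LOD reaches the strict critical value and its Mendelian mismatches stay
#' within `floor(max_mismatch_frac * L)` for the L-locus panel (one locus
#' in twenty at the default). Offspring left
#' unresolved are then given the single-parent analysis under the same
#' rules. Offspring typed at fewer than `min_typed_loci` loci are skipped
#' with a warning.
#'
#' @param gt Genotype table holding offspring and candidates.
#' @param offspring_ids,candidate_ids Accession ids (an offspring present
#'   among the candidates is never matched to itself).
#' @param loci Loci to use (typically the diversity/parentage panel minus
#'   loci flagged for null alleles, see [parentage_panel()]).
#' @param critical A [simulate_critical_lod()] result, or a single number
#'   used as the threshold for both analyses.
#' @param eps Per-genotype error rate.
#' @param max_mismatch_frac Mismatch budget as a fraction of the panel
#'   size (default 0.05, i.e. one locus in twenty).
#' @param min_typed_loci Minimal typed loci per offspring (default 10).
#' @param freqs Optional precomputed allele frequencies (defaults to
#'   frequencies over the candidate set).
#' @return Tibble: `offspring`, `parent1`, `parent2` (`NA` for duos),
#'   `type`, `loci_compared`, `mismatches`, `lod`, `confidence`
#'   (`"strict95"`, `"relaxed80"` or `"none"`), `maternal`
#'   (`"undetermined"` until [designate_mother()] is applied).
#' @export
assign_parentage <- function(gt, offspring_ids, candidate_ids, loci = NULL,
                             critical, eps = 0.01, max_mismatch_frac = 0.05,
                             min_typed_loci = 10, freqs = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  cand <- gt[match(candidate_ids, gt$id), ]
  freqs <- freqs %||% allele_frequencies(cand, loci)
  pk <- pk_data(cand, loci, freqs)
  crit <- extract_critical(critical)
  al <- gt_alleles(gt, loci)
  off_rows <- match(offspring_ids, gt$id)
  typed_counts <- rowSums(!is.na(al$a1[off_rows, , drop = FALSE]))
  skip <- typed_counts < min_typed_loci
  if (any(skip)) {
    warn(paste0("Skipping offspring typed at < ", min_typed_loci, " loci: ",
                paste(offspring_ids[skip], collapse = ", ")))
  }
  keep_ids <- offspring_ids[!skip]
  if (!length(keep_ids)) return(empty_parentage())
  enc_off <- encode_offspring(gt, keep_ids, loci, pk)
  pk <- enc_off$pk
  excl <- match(keep_ids, candidate_ids)
  sc <- parentage_scores(pk, enc_off$o1, enc_off$o2, eps,
                         top_m = length(candidate_ids),
                         exclude_self = excl, full_pairs = TRUE)
  budget_panel <- floor(max_mismatch_frac * length(loci))
  res <- lapply(seq_along(keep_ids), function(o) {
    budget <- function(nloci) budget_panel
    # trio first
    if (!is.na(sc$trio_lod[o]) &&
        sc$trio_lod[o] >= crit["trio_strict"] &&
        sc$trio_mm[o] <= budget(sc$trio_n[o])) {
      conf <- if (sc$trio_lod[o] >= crit["trio_strict"]) "strict95" else "relaxed80"
      return(tibble(offspring = keep_ids[o],
                    parent1 = pk$ids[sc$trio_best_a[o]],
                    parent2 = pk$ids[sc$trio_best_b[o]],
                    type = "trio",
                    loci_compared = sc$trio_n[o], mismatches = sc$trio_mm[o],
                    lod = sc$trio_lod[o], confidence = conf,
                    maternal = "undetermined"))
    }
    if (!is.na(sc$trio_lod[o]) &&
        sc$trio_lod[o] >= crit["trio_relaxed"] &&
        sc$trio_mm[o] <= budget(sc$trio_n[o])) {
      return(tibble(offspring = keep_ids[o],
                    parent1 = pk$ids[sc$trio_best_a[o]],
                    parent2 = pk$ids[sc$trio_best_b[o]],
                    type = "trio",
                    loci_compared = sc$trio_n[o], mismatches = sc$trio_mm[o],
                    lod = sc$trio_lod[o], confidence = "relaxed80",
                    maternal = "undetermined"))
    }
    # duo
    db <- sc$duo_best[o]
    if (!is.na(db)) {
      dn <- sc$single_n[o, db]; dm <- sc$single_mm[o, db]
      dl <- sc$duo_lod[o]
      if (dn > 0 && dm <= budget(dn) && dl >= crit["duo_relaxed"]) {
        conf <- if (dl >= crit["duo_strict"]) "strict95" else "relaxed80"
        return(tibble(offspring = keep_ids[o], parent1 = pk$ids[db],
                      parent2 = NA_character_, type = "duo",
                      loci_compared = dn, mismatches = dm, lod = dl,
                      confidence = conf, maternal = "undetermined"))
      }
    }
    tibble(offspring = keep_ids[o], parent1 = NA_character_,
           parent2 = NA_character_, type = "none",
           loci_compared = typed_counts[!skip][o], mismatches = NA_integer_,
           lod = NA_real_, confidence = "none", maternal = "undetermined")
  })
  bind_rows(res)
}

empty_parentage <- function() {
  tibble(offspring = character(), parent1 = character(), parent2 = character(),
         type = character(), loci_compared = integer(), mismatches = integer(),
         lod = double(), confidence = character(), maternal = character())
}

extract_critical <- function(critical) {
  if (is.numeric(critical) && length(critical) == 1) {
    return(c(trio_strict = critical, trio_relaxed = critical,
             duo_strict = critical, duo_relaxed = critical))
  }
  if (inherits(critical, "vk_lodsim")) {
    pick <- function(an, lv) {
      v <- critical$critical_lod[critical$analysis == an & critical$level == lv]
      if (length(v)) v else Inf
    }
    return(c(trio_strict = pick("trio", "strict95"),
             trio_relaxed = pick("trio", "relaxed80"),
             duo_strict = pick("duo", "strict95"),
             duo_relaxed = pick("duo", "relaxed80")))
  }
  abort("critical must be a number or a simulate_critical_lod() result.")
}

encode_offspring <- function(gt, ids, loci, pk) {
  rows <- match(ids, gt$id)
  L <- length(loci)
  o1 <- matrix(0L, length(ids), L); o2 <- matrix(0L, length(ids), L)
  for (j in seq_len(L)) {
    lev <- pk$enc$alleles[[loci[j]]]
    a1 <- as.character(gt[[paste0(loci[j], "_1")]][rows])
    a2 <- as.character(gt[[paste0(loci[j], "_2")]][rows])
    i1 <- match(a1, lev); i2 <- match(a2, lev)
    # offspring allele unseen among candidates: extend the frequency vector
    if (anyNA(i1[!is.na(a1)]) || anyNA(i2[!is.na(a2)])) {
      new_al <- setdiff(unique(stats::na.omit(c(a1, a2))), lev)
      lev <- c(lev, new_al)
      pk$enc$alleles[[loci[j]]] <- lev
      pk$enc$n_alleles[j] <- length(lev)
      floor_f <- min(pk$p[[j]]) / 2
      pk$p[[j]] <- c(pk$p[[j]], rep(floor_f, length(new_al)))
      pk$p[[j]] <- pk$p[[j]] / sum(pk$p[[j]])
      i1 <- match(a1, lev); i2 <- match(a2, lev)
    }
    o1[, j] <- ifelse(is.na(i1), 0L, pmin(i1, i2))
    o2[, j] <- ifelse(is.na(i1), 0L, pmax(i1, i2))
  }
  list(o1 = o1, o2 = o2, pk = pk)
}

#' Loci suitable for parentage analysis
#'
#' Drops loci whose estimated null-allele frequency exceeds `fnull_max`
#' (null alleles mimic exclusions) and monomorphic loci.
#'
#' @param stats A [locus_stats()] tibble.
#' @param fnull_max Exclusion threshold (default 0.1).
#' @return Character vector of locus names.
#' @export
parentage_panel <- function(stats, fnull_max = 0.1) {
  keep <- stats$na > 1 & (is.na(stats$fnull) | stats$fnull <= fnull_max)
  dropped <- stats$locus[!keep]
  if (length(dropped)) {
    inform(paste0("Excluded from parentage: ", paste(dropped, collapse = ", ")))
  }
  stats$locus[keep]
}

#' Screen for first-degree relative pairs
#'
#' Two individuals in a parent-offspring (or full-sib) relation share at
#' least one allele at every locus. The screen keeps pairs with enough
#' co-typed loci and at most `floor(max_mismatch_frac * L)` sharing
#' failures, and attaches the single-parent LOD (first id treated as the
#' offspring). Parent-offspring and full-sib pairs are indistinguishable
#' here without further data.
#'
#' @param gt Genotype table.
#' @param loci Loci to use.
#' @param eps Error rate for the LOD.
#' @param max_mismatch_frac Tolerated fraction of non-sharing loci.
#' @param freqs Optional precomputed allele frequencies.
#' @return Tibble `id_a`, `id_b`, `loci_compared`, `mismatch_loci`, `lod`.
#' @export
halfkin_screen <- function(gt, loci = NULL, eps = 0.01,
                           max_mismatch_frac = 0.05, freqs = NULL) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  L <- length(loci)
  budget <- floor(max_mismatch_frac * L)
  min_typed <- L - budget
  al <- gt_alleles(gt, loci)
  freqs <- freqs %||% allele_frequencies(gt, loci)
  n <- nrow(gt)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(al$a1[i, ]) & !is.na(al$a1[j, ])
      lc <- sum(ok)
      if (lc < min_typed) next
      sh <- shared_alleles(al$a1[i, ok], al$a2[i, ok], al$a1[j, ok], al$a2[j, ok])
      fails <- sum(sh == 0)
      if (fails > budget) next
      lod <- lod_parentage(gt, gt$id[i], gt$id[j], loci = loci,
                           eps = eps, freqs = freqs)$lod
      rows[[length(rows) + 1]] <- tibble(id_a = gt$id[i], id_b = gt$id[j],
                                         loci_compared = lc,
                                         mismatch_loci = fails, lod = lod)
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(id_a = character(), id_b = character(), loci_compared = integer(),
           mismatch_loci = integer(), lod = double())
}
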
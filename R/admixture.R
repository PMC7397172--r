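#' Bayesian admixture inference by Gibbs sampling
#'
#' Fits the standard admixture model: each individual draws each allele
#' copy from one of `K` ancestral populations according to its ancestry
#' vector Q (symmetric Dirichlet(alpha) prior, alpha updated by
#' Metropolis), and each population carries its own allele frequencies --
#' either independent Dirichlet(`lambda`) per population, or the
#' correlated F-model in which population frequencies are
#' Dirichlet-dispersed around an ancestral frequency vector with a
#' per-population drift parameter. The model log-probability is estimated
#' from the post-burn-in log-likelihood trace as
#' `mean(loglik) - var(loglik)/2`.
#'
#' @param gt Genotype table (nuclear loci).
#' @param K Number of ancestral populations (>= 1).
#' @param loci Loci to use; default all nuclear loci.
#' @param iters Post-burn-in sweeps (default 2000).
#' @param burnin Burn-in sweeps (default 2000). The classic long-run
#'   preset (150000/150000) is available via
#'   `vk_mcmc_preset("publication")`.
#' @param seed Integer seed (required: runs are reproducible).
#' @param freq_model `"correlated"` (default) or `"independent"`.
#' @param alpha0 Initial alpha (default 1); uniform prior on (0, 10].
#' @param lambda Dirichlet parameter of the independent model (default 1).
#' @return A `vk_admixture`: list with `K`, `Q` (tibble `id` + `Q1..QK`),
#'   `P` (per-locus posterior-mean frequencies), `lnPXK`, `loglik`,
#'   `alpha_trace`, `seed`, `iters`, `burnin`, `loci`.
#' @export
run_admixture <- function(gt, K, loci = NULL, iters = 2000, burnin = 2000,
                          seed = NULL, freq_model = c("correlated", "independent"),
                          alpha0 = 1, lambda = 1) {
  panel <- gt_panel(gt)
  loci <- loci %||% nuclear_loci(panel)
  freq_model <- match.arg(freq_model)
  if (K < 1) abort("K must be >= 1.")
  if (iters < 1 || burnin < 0) abort("iters must be > 0 and burnin >= 0.")
  if (is.null(seed)) abort("Provide an integer `seed`: admixture runs are seeded.")
  enc <- encode_alleles(gt, loci)
  set.seed(seed)
  res <- admix_gibbs_cpp(enc$geno, enc$n_alleles, as.integer(K),
                         as.integer(burnin), as.integer(iters),
                         lambda, alpha0, 10.0, 0.05,
                         freq_model == "correlated", 0.1, 0.1, 500.0)
  ll <- res$loglik
  lnPXK <- mean(ll) - stats::var(ll) / 2
  at <- res$alpha_trace
  # crude non-convergence flag: alpha still drifting monotonically late on
  if (K > 1 && length(at) >= 200) {
    tail_at <- at[seq(round(length(at) * 0.6), length(at))]
    dr <- diff(tail_at)
    moved <- abs(tail_at[length(tail_at)] - tail_at[1]) > 0.5
    if (moved && (all(dr >= 0) || all(dr <= 0))) {
      warn("alpha trace drifts monotonically over the late run; consider more sweeps.")
    }
  }
  Q <- as_tibble(as.data.frame(res$Q))
  names(Q) <- paste0("Q", seq_len(K))
  P <- res$P
  names(P) <- loci
  for (l in loci) colnames(P[[l]]) <- enc$alleles[[l]]
  structure(list(K = K, Q = bind_cols(tibble(id = gt$id), Q), P = P,
                 lnPXK = lnPXK, loglik = ll, alpha_trace = at,
                 alpha_accept = res$alpha_accept, F_drift = res$F,
                 seed = seed, iters = iters, burnin = burnin,
                 freq_model = freq_model, loci = loci),
            class = "vk_admixture")
}

# recode nuclear genotypes as integer allele indices; 0 = missing
encode_alleles <- function(gt, loci) {
  al <- gt_alleles(gt, loci)
  n <- nrow(gt); L <- length(loci)
  geno <- matrix(0L, n, 2 * L)
  alleles <- vector("list", L); names(alleles) <- loci
  for (j in seq_len(L)) {
    l <- loci[j]
    lev <- sort(unique(stats::na.omit(c(al$a1[, l], al$a2[, l]))))
    alleles[[l]] <- lev
    geno[, 2 * j - 1] <- ifelse(is.na(al$a1[, l]), 0L, match(al$a1[, l], lev))
    geno[, 2 * j] <- ifelse(is.na(al$a2[, l]), 0L, match(al$a2[, l], lev))
  }
  list(geno = geno, n_alleles = vapply(alleles, length, 1L), alleles = alleles)
}

#' MCMC length presets
#'
#' `"desk"` (2000 burn-in + 2000 sweeps) for interactive work and tests;
#' `"publication"` (150000 + 150000) for final long runs.
#'
#' @param name Preset name.
#' @return List with `burnin` and `iters`.
#' @export
vk_mcmc_preset <- function(name = c("desk", "publication")) {
  switch(match.arg(name),
         desk = list(burnin = 2000L, iters = 2000L),
         publication = list(burnin = 150000L, iters = 150000L))
}

#' @export
print.vk_admixture <- function(x, ...) {
  cat("# Admixture fit: K = ", x$K, ", ", nrow(x$Q), " individuals, ",
      length(x$loci), " loci, ", x$freq_model, " frequencies\n", sep = "")
  cat("# lnP(X|K) = ", round(x$lnPXK, 2), " (", x$iters, " sweeps after ",
      x$burnin, " burn-in; seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.vk_admixture <- function(x, ...) {
  tidyr::pivot_longer(x$Q, -"id", names_to = "population",
                      values_to = "q", names_prefix = "Q")
}

#' @export
glance.vk_admixture <- function(x, ...) {
  tibble(K = x$K, lnPXK = x$lnPXK,
         mean_loglik = mean(x$loglik),
         alpha = mean(x$alpha_trace[seq(length(x$alpha_trace) / 2, length(x$alpha_trace))]),
         iters = x$iters, burnin = x$burnin, seed = x$seed)
}

#' Stacked ancestry bar plot
#' @param object A `vk_admixture`.
#' @param order_by Population whose Q sorts the bars (default `1`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vk_admixture <- function(object, order_by = 1, ...) {
  long <- tidy(object)
  ord <- object$Q$id[order(-object$Q[[paste0("Q", order_by)]])]
  long$id <- factor(long$id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$q,
                                     fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry (Q)", fill = "pop") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
}

#' Evanno table for choosing K
#'
#' Summarises replicate admixture runs across consecutive K: mean and sd of
#' lnP(X|K), and the second-difference statistic
#' `deltaK = mean(|L(K-1) - 2 L(K) + L(K+1)|) / sd(L(K))`, defined for
#' interior K with positive sd. The K maximising deltaK is reported as the
#' suggestion; the mean-lnP curve is kept alongside so both criteria can be
#' read.
#'
#' @param fits List of `vk_admixture` fits covering >= 3 consecutive K
#'   values with >= 2 replicates each.
#' @return A `vk_evanno` tibble: `K`, `n_reps`, `mean_lnpk`, `sd_lnpk`,
#'   `delta_k`, with attribute `"suggested_k"`.
#' @export
evanno <- function(fits) {
  ln <- tibble(K = vapply(fits, function(f) f$K, 1),
               lnpk = vapply(fits, function(f) f$lnPXK, 1))
  ks <- sort(unique(ln$K))
  if (length(ks) < 3 || !all(diff(ks) == 1)) {
    abort("Need >= 3 consecutive K values.")
  }
  reps <- table(ln$K)
  if (any(reps < 2)) abort("Need >= 2 replicates per K.")
  agg <- ln |> group_by(.data$K) |>
    summarise(n_reps = n(), mean_lnpk = mean(.data$lnpk),
              sd_lnpk = sd(.data$lnpk), .groups = "drop") |>
    arrange(.data$K)
  # mean |L''(K)| over replicates needs replicate-level second differences;
  # with independent replicates the standard estimator uses the means:
  # |mean L(K-1) - 2 mean L(K) + mean L(K+1)| / sd(L(K))
  m <- agg$mean_lnpk
  dk <- rep(NA_real_, nrow(agg))
  for (i in seq(2, nrow(agg) - 1)) {
    if (agg$sd_lnpk[i] > 0) {
      dk[i] <- abs(m[i - 1] - 2 * m[i] + m[i + 1]) / agg$sd_lnpk[i]
    }
  }
  agg$delta_k <- dk
  if (all(is.na(dk))) {
    warn("deltaK undefined everywhere (zero replicate sd).")
    suggested <- NA_integer_
  } else {
    suggested <- agg$K[which.max(dk)]
  }
  structure(agg, suggested_k = suggested, class = c("vk_evanno", class(agg)))
}

#' @export
print.vk_evanno <- function(x, ...) {
  NextMethod()
  cat("# suggested K (max deltaK):", attr(x, "suggested_k"), "\n")
  invisible(x)
}

#' @export
autoplot.vk_evanno <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Align replicate Q matrices across label switching
#'
#' Population labels are arbitrary per run. Replicates are aligned to an
#' accumulating reference by choosing, for each, the column permutation
#' maximising the pairwise similarity
#' `G = 1 - ||Q_a - Q_b||_F / sqrt(2 n)`; the search is exhaustive for
#' K <= 7 and greedy (best column pairing) beyond, repeated over `reps`
#' random replicate orders keeping the best total G.
#'
#' @param q_list List of Q matrices (or `vk_admixture` fits) of equal shape.
#' @param reps Random restarts over input orders (default 100).
#' @param seed Seed for restart order.
#' @return List with `aligned` (list of matrices), `mean_q`, `perms`, `G`.
#' @export
align_replicates <- function(q_list, reps = 100, seed = 1) {
  qm <- lapply(q_list, function(q) {
    if (inherits(q, "vk_admixture")) q <- q$Q
    if (is.data.frame(q)) {
      qc <- grep("^Q[0-9]*$", names(q))
      if (length(qc)) q <- q[, qc, drop = FALSE]
    }
    unname(as.matrix(q))
  })
  dims <- vapply(qm, dim, c(1L, 1L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All Q matrices must have the same shape.")
  }
  K <- ncol(qm[[1]]); n <- nrow(qm[[1]]); R <- length(qm)
  if (R == 1) return(list(aligned = qm, mean_q = qm[[1]],
                          perms = list(seq_len(K)), G = 1))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(reps)) {
    ord <- if (r == 1) seq_len(R) else sample(R)
    ref <- qm[[ord[1]]]
    acc <- ref
    perms <- vector("list", R); perms[[ord[1]]] <- seq_len(K)
    gsum <- 0
    for (idx in seq(2, R)) {
      i <- ord[idx]
      pm <- best_permutation(qm[[i]], acc / (idx - 1))
      perms[[i]] <- pm$perm
      acc <- acc + qm[[i]][, pm$perm, drop = FALSE]
      gsum <- gsum + pm$G
    }
    if (is.null(best) || gsum > best$gsum) {
      best <- list(perms = perms, gsum = gsum, first = ord[1])
    }
  }
  aligned <- lapply(seq_len(R), function(i) qm[[i]][, best$perms[[i]], drop = FALSE])
  mean_q <- Reduce(`+`, aligned) / R
  G <- mean(vapply(aligned, function(a) g_similarity(a, mean_q), 1))
  list(aligned = aligned, mean_q = mean_q, perms = best$perms, G = G)
}

g_similarity <- function(qa, qb) {
  1 - sqrt(sum((qa - qb)^2)) / sqrt(2 * nrow(qa))
}

best_permutation <- function(q, ref) {
  K <- ncol(q)
  if (K <= 7) {
    perms <- all_perms(K)
    gs <- vapply(perms, function(p) g_similarity(q[, p, drop = FALSE], ref), 1)
    i <- which.max(gs)
    list(perm = perms[[i]], G = gs[i])
  } else {
    # greedy pairing on squared-error gain
    cost <- outer(seq_len(K), seq_len(K),
                  Vectorize(function(a, b) sum((q[, a] - ref[, b])^2)))
    perm <- integer(K); used <- rep(FALSE, K)
    for (step in seq_len(K)) {
      cc <- cost; cc[used, ] <- Inf; cc[, perm[perm > 0]] <- Inf
      ij <- which(cc == min(cc), arr.ind = TRUE)[1, ]
      perm[ij[2]] <- ij[1]; used[ij[1]] <- TRUE
    }
    list(perm = perm, G = g_similarity(q[, perm, drop = FALSE], ref))
  }
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_perms(k - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  }
  out
}

#' Assign individuals to populations by a Q threshold
#'
#' An individual is assigned to its majority population when that
#' population's Q is at or above `threshold` (inclusive); otherwise it is
#' called `"admixed"`.
#'
#' @param Q Q tibble (`id` + `Q1..QK`) or a `vk_admixture`.
#' @param threshold Assignment threshold in (0.5, 1]; default 0.75.
#' @return Tibble `id`, `assignment` (`"pop<k>"` or `"admixed"`), `max_q`.
#' @export
assign_membership <- function(Q, threshold = 0.75) {
  if (inherits(Q, "vk_admixture")) Q <- Q$Q
  if (threshold <= 0.5 || threshold > 1) abort("threshold must be in (0.5, 1].")
  qm <- as.matrix(Q[, grep("^Q", names(Q)), drop = FALSE])
  k <- max.col(qm, ties.method = "first")
  mq <- qm[cbind(seq_len(nrow(qm)), k)]
  tibble(id = Q$id,
         assignment = ifelse(mq >= threshold, paste0("pop", k), "admixed"),
         max_q = mq)
}
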
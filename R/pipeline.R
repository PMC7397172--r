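#' Configure an end-to-end characterization run
#'
#' One declarative configuration drives the whole pipeline in the standard
#' order: fingerprint/dedupe on the cat.1 panel, per-locus statistics and
#' the -ln(PSA)/UPGMA tree on the diversity panel (cat.1+2), admixture
#' structure scans with Evanno and AMOVA, simulation-calibrated parentage
#' on the diversity panel minus null-allele loci, and chlorotype
#' assignment. Every stochastic stage carries an explicit seed, so a rerun
#' with the same configuration reproduces every number.
#'
#' @param table A `vk_geno` genotype table (or a CSV path plus `panel`).
#' @param panel Panel used when `table` is a path.
#' @param out_dir Output directory for the report bundle.
#' @param stages Character subset of
#'   `c("dedupe","stats","tree","structure","amova","parentage","chlorotype")`.
#' @param chlorotype_map A [chlorotype_map()] or `NULL` (stage skipped
#'   with a notice).
#' @param metadata Optional accession metadata (`id`, `region`, ...).
#' @param max_mismatch Duplicate tolerance in alleles (default 2).
#' @param q_threshold Membership threshold (default 0.75).
#' @param k_range K values for the structure scan.
#' @param structure_reps Replicates per K.
#' @param mcmc [vk_mcmc_preset()] or a list with `burnin`, `iters`.
#' @param n_sim_offspring Simulated offspring for the critical LOD.
#' @param max_mismatch_frac Parentage mismatch budget.
#' @param error_rate Assumed genotyping error rate.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return A `vk_run_config` list.
#' @export
run_config <- function(table, panel = NULL, out_dir = tempfile("vinekin_run_"),
                       stages = c("dedupe", "stats", "tree", "structure",
                                  "amova", "parentage", "chlorotype"),
                       chlorotype_map = NULL, metadata = NULL,
                       max_mismatch = 2, q_threshold = 0.75,
                       k_range = 1:4, structure_reps = 2,
                       mcmc = list(burnin = 500, iters = 500),
                       n_sim_offspring = 2000, max_mismatch_frac = 0.05,
                       error_rate = 0.01, seed = 1) {
  if (is.character(table)) {
    if (is.null(panel)) abort("Reading from CSV needs a `panel`.")
    table <- read_genotype_csv(table, panel)
  }
  structure(list(table = table, out_dir = out_dir, stages = stages,
                 chloromap = chlorotype_map, metadata = metadata,
                 max_mismatch = max_mismatch, q_threshold = q_threshold,
                 k_range = k_range, structure_reps = structure_reps,
                 mcmc = mcmc, n_sim_offspring = n_sim_offspring,
                 max_mismatch_frac = max_mismatch_frac,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "vk_run_config")
}

#' Run the full characterization pipeline
#'
#' Executes the configured stages in order, writes each artifact as a
#' plain-text file with a provenance header (package version, stage, seed),
#' and returns the in-memory results. A failing stage aborts with its name
#' while earlier artifacts stay on disk.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of stage results (also written under
#'   `cfg$out_dir`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "vk_run_config")) abort("cfg must come from run_config().")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- cfg$table
  panel <- gt_panel(gt)
  results <- list()
  log_lines <- c(sprintf("vinekin %s pipeline; master seed %d",
                         as.character(utils::packageVersion("vinekin")), cfg$seed),
                 sprintf("input: %d accessions x %d loci", nrow(gt), nrow(panel)))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    inform(sprintf(...))
  }
  stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(force(expr),
             error = function(e) abort(paste0("Stage '", name, "' failed: ",
                                              conditionMessage(e))))
  }

  # --- dedupe ------------------------------------------------------------
  stage("dedupe", {
    rep <- find_duplicates(gt, max_mismatch = cfg$max_mismatch)
    results$dedupe <- rep
    reps <- rep$groups$id[rep$groups$representative]
    say("dedupe: %d accessions in, %d identity groups, %d duplicates removed",
        nrow(gt), length(reps), nrow(gt) - length(reps))
    write_with_header(rep$pairs, file.path(cfg$out_dir, "duplicate_pairs.csv"),
                      "dedupe", cfg$seed)
    write_with_header(rep$groups, file.path(cfg$out_dir, "identity_groups.csv"),
                      "dedupe", cfg$seed)
    gt <- gt[gt$id %in% reps, ]
    attr(gt, "panel") <- panel
  })

  # --- stats -------------------------------------------------------------
  div_loci <- intersect(panel_loci(panel, category = c("cat1", "cat2")),
                        nuclear_loci(panel))
  if (!length(div_loci)) div_loci <- nuclear_loci(panel)
  stats <- NULL
  stage("stats", {
    stats <- locus_stats(gt, loci = div_loci, seed = cfg$seed + 1)
    results$stats <- stats
    results$panel_summary <- panel_summary(stats)
    results$cumulative_pid <- cumulative_pid(stats)
    say("stats: %d loci, mean He %.3f, cumulative P(ID)u %.3g",
        nrow(stats), mean(stats$he), results$cumulative_pid$cum_pid_u)
    write_with_header(as_tibble(stats), file.path(cfg$out_dir, "locus_stats.csv"),
                      "stats", cfg$seed + 1)
  })

  # --- tree --------------------------------------------------------------
  stage("tree", {
    dm <- psa_distance(gt, loci = div_loci)
    tree <- upgma(dm)
    results$distance <- dm
    results$tree <- tree
    say("tree: UPGMA over %d accessions, root height %.4f", nrow(gt), tree$height)
    writeLines(c(provenance_header("tree", cfg$seed), tree$newick),
               file.path(cfg$out_dir, "upgma.nwk"))
    write_with_header(tidy(dm), file.path(cfg$out_dir, "distances.csv"),
                      "tree", cfg$seed)
  })

  # --- structure ---------------------------------------------------------
  stage("structure", {
    fits <- list()
    for (K in cfg$k_range) {
      for (r in seq_len(cfg$structure_reps)) {
        fits[[length(fits) + 1]] <-
          run_admixture(gt, K, loci = div_loci,
                        iters = cfg$mcmc$iters, burnin = cfg$mcmc$burnin,
                        seed = cfg$seed + 100 * K + r)
      }
    }
    results$structure <- fits
    ev <- try(evanno(fits), silent = TRUE)
    if (!inherits(ev, "try-error")) {
      results$evanno <- ev
      say("structure: K scan %s, suggested K = %s",
          paste(range(cfg$k_range), collapse = ".."),
          attr(ev, "suggested_k"))
      write_with_header(as_tibble(ev), file.path(cfg$out_dir, "evanno.csv"),
                        "structure", cfg$seed)
      bestK <- attr(ev, "suggested_k")
    } else {
      bestK <- max(cfg$k_range)
    }
    best_fits <- Filter(function(f) f$K == bestK, fits)
    al <- align_replicates(best_fits, seed = cfg$seed)
    meanq <- bind_cols(tibble(id = gt$id),
                       as_tibble(setNames(as.data.frame(al$mean_q),
                                          paste0("Q", seq_len(bestK)))))
    results$membership <- assign_membership(meanq, cfg$q_threshold)
    readr::write_tsv(meanq, file.path(cfg$out_dir, "q_matrix.tsv"))
    write_with_header(results$membership,
                      file.path(cfg$out_dir, "membership.csv"),
                      "structure", cfg$seed)
  })

  # --- amova -------------------------------------------------------------
  stage("amova", {
    if (is.null(results$membership) || is.null(results$distance)) {
      say("amova: skipped (needs structure + tree stages)")
    } else {
      assigned <- results$membership[results$membership$assignment != "admixed", ]
      if (length(unique(assigned$assignment)) >= 2) {
        keep <- match(assigned$id, rownames(results$distance$d))
        d <- results$distance$d[keep, keep]
        am <- amova(d, setNames(assigned$assignment, assigned$id),
                    seed = cfg$seed + 7)
        results$amova <- am
        say("amova: Phi_PT %.3f (p = %.4g)", am$phi_pt, am$p_value)
        write_with_header(glance(am), file.path(cfg$out_dir, "amova.csv"),
                          "amova", cfg$seed + 7)
      } else {
        say("amova: skipped (fewer than two assigned groups)")
      }
    }
  })

  # --- parentage ---------------------------------------------------------
  stage("parentage", {
    loci_par <- if (!is.null(stats)) parentage_panel(stats) else div_loci
    sim <- simulate_critical_lod(
      gt, loci = loci_par,
      cfg = parentage_sim_config(n_offspring = cfg$n_sim_offspring,
                                 error_rate = cfg$error_rate),
      seed = cfg$seed + 11)
    res <- assign_parentage(gt, gt$id, gt$id, loci = loci_par,
                            critical = sim, eps = cfg$error_rate,
                            max_mismatch_frac = cfg$max_mismatch_frac,
                            min_typed_loci = min(10, length(loci_par)))
    results$critical_lod <- sim
    results$parentage <- res
    say("parentage: %d trios, %d duos accepted of %d offspring screened",
        sum(res$type == "trio"), sum(res$type == "duo"), nrow(res))
    write_with_header(res, file.path(cfg$out_dir, "parentage.csv"),
                      "parentage", cfg$seed + 11)
  })

  # --- chlorotype --------------------------------------------------------
  stage("chlorotype", {
    if (is.null(cfg$chloromap)) {
      say("chlorotype: skipped (no map configured)")
    } else {
      chl <- assign_chlorotype(gt, cfg$chloromap)
      results$chlorotype <- chl
      results$chlorotype_freq <- chlorotype_frequencies(chl, cfg$metadata)
      if (!is.null(results$parentage)) {
        results$parentage <- designate_mother(results$parentage, chl)
        write_with_header(results$parentage,
                          file.path(cfg$out_dir, "parentage.csv"),
                          "parentage", cfg$seed + 11)
      }
      say("chlorotype: %d assigned, %d n.d.",
          sum(chl$chlorotype != "n.d."), sum(chl$chlorotype == "n.d."))
      write_with_header(chl, file.path(cfg$out_dir, "chlorotypes.csv"),
                        "chlorotype", cfg$seed)
    }
  })

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(results)
}

provenance_header <- function(stage, seed) {
  sprintf("# vinekin %s | stage %s | seed %d",
          as.character(utils::packageVersion("vinekin")), stage, seed)
}

write_with_header <- function(df, path, stage, seed) {
  writeLines(provenance_header(stage, seed), path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}
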
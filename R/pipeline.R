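# End-to-end orchestration: run every analysis stage on one alignment +
# population map and write the full table set. No statistic is computed
# here; every number comes from the stage functions.

#' Run the full single-locus analysis pipeline
#'
#' Stages: diversity table, neutrality tests, mismatch/expansion analysis,
#' one-level AMOVA, SAMOVA (K = 2), pairwise Phi_ST, between-population
#' K2P distances with UPGMA and NJ trees, and the haplotype network. All
#' outputs are written under `out_dir`; a run log records the seed and
#' every parameter.
#'
#' @param alignment Path to a FASTA alignment or a `coi_alignment`.
#' @param popmap Path to a population map CSV or a `coi_popmap`.
#' @param out_dir Output directory.
#' @param clock A `coi_clock` for expansion times.
#' @param permutations Permutations for AMOVA / pairwise tests.
#' @param reps Replicates for neutrality p-values and mismatch bootstrap.
#' @param seed Integer seed (recorded in the log).
#' @param samova_k Number of SAMOVA groups (default 2).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage result.
#' @export
run_all <- function(alignment, popmap, out_dir,
                    clock = mutation_clock(), permutations = 1000,
                    reps = 1000, seed = 42, samova_k = 2, quiet = FALSE) {
  stage <- function(name, expr) {
    if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"), "] ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  aln <- if (inherits(alignment, "coi_alignment")) alignment else
    stage("read alignment", read_alignment(alignment))
  pm <- if (inherits(popmap, "coi_popmap")) popmap else
    stage("read population map", read_population_map(popmap))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)

  ht <- stage("haplotypes", collapse_haplotypes(aln, pm))
  write_haplotype_table(ht, file.path(out_dir, "haplotypes.csv"))

  div <- stage("diversity", diversity_table(aln, pm))
  write_results_table(div, file.path(out_dir, "diversity.csv"))

  neut <- stage("neutrality",
                neutrality_table(aln, pm, reps = reps, seed = seed))
  write_results_table(neut, file.path(out_dir, "neutrality.csv"),
                      digits = 3)

  mism <- stage("mismatch", mismatch_table(aln, pm, clock = clock,
                                           reps = reps, seed = seed))
  write_results_table(mism$table, file.path(out_dir, "mismatch.csv"))
  for (p in names(mism$histograms)) {
    h <- mism$histograms[[p]]
    utils::write.csv(data.frame(differences = seq_along(h$observed) - 1L,
                                observed = h$observed,
                                expected = h$expected),
                     file.path(out_dir, paste0("mismatch_hist_", p,
                                               ".csv")),
                     row.names = FALSE)
  }

  d2 <- stage("pairwise differences", pairwise_difference_matrix(aln))
  pops <- pop_labels(aln, pm)
  am <- stage("amova", amova(d2, pops, permutations = permutations,
                             seed = seed))
  sam <- stage("samova", samova(d2, pops, K = samova_k,
                                permutations = permutations, seed = seed))
  pw <- stage("pairwise phi_st",
              pairwise_phist(d2, pops, permutations = permutations,
                             seed = seed))
  write_amova_csv(am, sam, file.path(out_dir, "amova.csv"))
  utils::write.csv(round(pw$phi_st, 4),
                   file.path(out_dir, "pairwise_phist.csv"))
  utils::write.csv(round(pw$p_values, 4),
                   file.path(out_dir, "pairwise_phist_p.csv"))

  ds <- stage("K2P distances", between_population_distance(aln, pm))
  utils::write.csv(round(ds$between, 4),
                   file.path(out_dir, "ds_matrix.csv"))
  trees <- stage("trees", list(upgma = upgma_tree(ds$between),
                               nj = nj_tree(ds$between)))
  write_newick(trees$upgma, file.path(out_dir, "upgma.nwk"))
  write_newick(trees$nj, file.path(out_dir, "nj.nwk"))

  net <- stage("network", build_tcs_network(ht))
  write_network(net, file.path(out_dir, "network.graphml"))

  log_lines <- c(
    paste0("coipopgen run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R ", R.version.string),
    paste0("seed=", seed, " permutations=", permutations, " reps=", reps,
           " samova_k=", samova_k),
    paste0("clock: rate=", clock$rate_per_site_per_year, "/site/year, ",
           "generation=", clock$generation_time_years, "y, sites=",
           clock$sites),
    paste0("samples=", length(aln$ids), " sites=", aln$length,
           " haplotypes=", length(ht$haplotype_id)),
    "conventions: complete deletion for S/K/pi; pairwise deletion for K2P",
    paste0("network connection limit=", net$limit, " steps"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(alignment = aln, popmap = pm, haplotypes = ht,
                 diversity = div, neutrality = neut, mismatch = mism,
                 amova = am, samova = sam, pairwise = pw,
                 distances = ds, trees = trees, network = net))
}

# Table-4-style CSV: one-level AMOVA block then the SAMOVA block
write_amova_csv <- function(am, sam, path) {
  row <- function(design, stratum, df, ss, sigma, pct, phi = "", p = "") {
    data.frame(design = design, stratum = stratum, df = df,
               SS = round(ss, 3),
               variance = ifelse(is.na(sigma), "", round(sigma, 4)),
               percent = ifelse(is.na(pct), "", round(pct, 2)),
               phi = phi, p = p, stringsAsFactors = FALSE)
  }
  blocks <- list()
  strata <- names(am$SS)
  for (s in strata) {
    blocks[[length(blocks) + 1L]] <- row(
      "AMOVA", s, am$df[[s]], am$SS[[s]],
      if (s %in% names(am$sigma)) am$sigma[[s]] else NA,
      if (s %in% names(am$percent)) am$percent[[s]] else NA,
      if (s == "among_populations") paste0("phi_ST=",
                                           round(am$phi[["phi_ST"]], 4))
      else "",
      if (s == "among_populations" && length(am$p_values)) {
        am$p_values[["phi_ST"]]
      } else "")
  }
  am2 <- sam$amova
  for (s in names(am2$SS)) {
    blocks[[length(blocks) + 1L]] <- row(
      "SAMOVA", s, am2$df[[s]], am2$SS[[s]],
      if (s %in% names(am2$sigma)) am2$sigma[[s]] else NA,
      if (s %in% names(am2$percent)) am2$percent[[s]] else NA)
  }
  phi_line <- paste(names(am2$phi), round(am2$phi, 4), sep = "=",
                    collapse = "; ")
  grp_line <- paste(names(sam$groups), sam$groups, sep = ":",
                    collapse = "; ")
  df <- do.call(rbind, blocks)
  utils::write.csv(df, path, row.names = FALSE)
  cat("# SAMOVA groups: ", grp_line, "\n# SAMOVA phi: ", phi_line, "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
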
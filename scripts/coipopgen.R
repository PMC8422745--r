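#!/usr/bin/env Rscript

# Thin command-line wrapper over the coipopgen package.
#
#   Rscript scripts/coipopgen.R <subcommand> [options]
#
# Subcommands:
#   simulate   --out DIR --seed INT
#   run-all    --alignment A.fasta --popmap pops.csv --out DIR --seed INT
#              [--permutations INT] [--reps INT] [--rate FLOAT]
#              [--gen-time FLOAT] [--samova-k INT]
#   trees      --distances ds.csv --out DIR        (e.g. a published matrix)
#
# Every analysis is a plain function call into the package; nothing is
# computed here.

suppressPackageStartupMessages(library(coipopgen))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: coipopgen.R <simulate|run-all|trees> [options]")
}
cmd <- args[1L]
opts <- args[-1L]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1L && i < length(opts)) return(opts[i + 1L])
  default
}

out_dir <- get_opt("--out", "coipopgen-out")
seed <- as.integer(get_opt("--seed", "42"))

if (cmd == "simulate") {
  fx <- make_fixture(out_dir, seed = seed)
  cat("fixture written to", out_dir, "\n")
} else if (cmd == "run-all") {
  aln <- get_opt("--alignment")
  pmp <- get_opt("--popmap")
  if (is.null(aln) || is.null(pmp)) {
    stop("run-all needs --alignment and --popmap")
  }
  clock <- mutation_clock(
    rate_per_site_per_year = as.numeric(get_opt("--rate", "1.4e-8")),
    generation_time_years = as.numeric(get_opt("--gen-time", "1.5")),
    sites = read_alignment(aln)$length)
  run_all(aln, pmp, out_dir,
          clock = clock,
          permutations = as.integer(get_opt("--permutations", "1000")),
          reps = as.integer(get_opt("--reps", "1000")),
          seed = seed,
          samova_k = as.integer(get_opt("--samova-k", "2")))
  cat("results written to", out_dir, "\n")
} else if (cmd == "trees") {
  dpath <- get_opt("--distances")
  if (is.null(dpath)) stop("trees needs --distances")
  dm <- read_distance_csv(dpath)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_newick(upgma_tree(dm), file.path(out_dir, "upgma.nwk"))
  write_newick(nj_tree(dm), file.path(out_dir, "nj.nwk"))
  cat("trees written to", out_dir, "\n")
} else {
  stop("unknown subcommand: ", cmd)
}
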
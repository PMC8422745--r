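test_that("theta = 0 yields identical sequences and zero diversity", {
  sim <- simulate_coalescent(sim_config(c(6L, 6L), L = 100, theta = 0,
                                        migration = 2, seed = 12))
  ht <- collapse_haplotypes(sim$alignment, sim$popmap)
  expect_equal(length(ht$haplotype_id), 1)
  expect_equal(site_summary(sim$alignment)$S, 0)
  expect_equal(haplotype_diversity(rowSums(ht$counts))$Hd, 0)
})

test_that("Watterson and pairwise theta estimates match the input rate", {
  set.seed(17)
  n <- 20
  a1 <- sum(1 / (1:(n - 1)))
  reps <- 500
  S <- numeric(reps)
  K <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- coipopgen:::sim_genealogy(n)
    m <- coipopgen:::branch_mutations(g, theta = 2)
    st <- coipopgen:::genealogy_stats(g, m)
    S[r] <- st$S
    K[r] <- st$K
  }
  expect_equal(mean(S) / a1, 2, tolerance = 0.1)
  expect_equal(mean(K), 2, tolerance = 0.1)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- sim_config(c(8L, 8L), L = 150, theta = 1.5, migration = 3,
                    seed = 77)
  s1 <- simulate_coalescent(cfg)
  s2 <- simulate_coalescent(cfg)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$popmap$assignments, s2$popmap$assignments)
})

test_that("island-model differentiation tracks 1/(1+2M)", {
  set.seed(19)
  reps <- 60
  phis <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- coipopgen:::sim_genealogy(c(20, 20), migration = 2)
    m <- coipopgen:::branch_mutations(g, theta = 2)
    d <- coipopgen:::genealogy_pairdiffs(g, m)
    rownames(d) <- colnames(d) <- paste0("s", 1:40)
    phis[r] <- amova(d, paste0("p", g$leaf_deme))$phi[["phi_ST"]]
  }
  expect_equal(mean(phis), 1 / (1 + 2 * 2), tolerance = 0.25)
})

test_that("the paper-like fixture meets its documented summary ranges", {
  dir <- file.path(tempdir(), "fixture-test")
  fx <- make_fixture(dir, seed = 123)
  aln <- read_alignment(fx$fasta)
  pm <- read_population_map(fx$popmap)
  expect_equal(length(aln$ids), 326)
  expect_equal(aln$length, 674)
  expect_equal(sort(as.integer(table(pm$assignments))),
               sort(c(46L, 44L, 47L, 47L, 48L, 48L, 46L)))

  pops <- unname(pm$assignments[aln$ids])
  ht <- collapse_haplotypes(aln, pm)
  hd <- vapply(colnames(ht$counts), function(p) {
    haplotype_diversity(ht$counts[, p])$Hd
  }, numeric(1))
  expect_true(all(hd >= 0.2 & hd <= 0.85))
  pis <- vapply(unique(pops), function(p) {
    nucleotide_diversity(coipopgen:::subset_alignment(aln,
                                                      pops == p))$pi
  }, numeric(1))
  expect_true(all(pis >= 3e-4 & pis <= 3e-3))

  d2 <- pairwise_difference_matrix(aln)
  pw <- pairwise_phist(d2, pops)
  jn <- pw$phi_st["JNlike", setdiff(colnames(pw$phi_st), "JNlike")]
  expect_true(all(jn > 0.4))

  # determinism on disk
  dir2 <- file.path(tempdir(), "fixture-test-2")
  fx2 <- make_fixture(dir2, seed = 123)
  expect_identical(readLines(fx$fasta), readLines(fx2$fasta))
})

test_that("fixture pipeline recovers structure and expansion signals", {
  dir <- file.path(tempdir(), "fixture-signal")
  fx <- make_fixture(dir, seed = 321)
  aln <- read_alignment(fx$fasta)
  pm <- read_population_map(fx$popmap)
  pops <- unname(pm$assignments[aln$ids])
  d2 <- pairwise_difference_matrix(aln)

  sam <- samova(d2, pops, K = 2, seed = 1)
  others <- setdiff(names(sam$groups), "JNlike")
  expect_false(sam$groups[["JNlike"]] %in% sam$groups[others])
  expect_equal(length(unique(sam$groups[others])), 1)

  # expansion signal: pooled D (diverged deme excluded) is negative
  sub <- coipopgen:::subset_alignment(aln, pops != "JNlike")
  ss <- site_summary(sub)
  nd <- nucleotide_diversity(sub)
  expect_lt(tajimas_d(nd$n, ss$S, nd$K), 0)
})
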
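test_that("pairwise difference matrices count mismatching sites", {
  aln <- new_alignment(c("a", "b", "c"), c("ACGT", "AGGA", "ACGT"))
  d <- pairwise_difference_matrix(aln)
  expect_equal(d["a", "b"], 2) # positions 2 and 4
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("AMOVA components match a direct expected-mean-square oracle", {
  for (sd in 1:4) {
    set.seed(sd)
    n <- 12
    pops <- sample(rep(c("A", "B", "C"), c(5, 4, 3)))
    d2 <- matrix(0, n, n, dimnames = list(paste0("s", 1:n),
                                          paste0("s", 1:n)))
    vals <- sample(0:6, n * (n - 1) / 2, replace = TRUE)
    d2[upper.tri(d2)] <- vals
    d2 <- d2 + t(d2)
    res <- amova(d2, pops)
    orc <- amova_oracle_onelevel(d2, pops)
    expect_equal(unname(res$SS), unname(orc$SS), tolerance = 1e-12)
    expect_equal(unname(res$sigma), unname(orc$sigma), tolerance = 1e-12)
    expect_equal(res$phi[["phi_ST"]], orc$phi_ST, tolerance = 1e-12)
    expect_equal(sum(res$percent), 100, tolerance = 0.01)
    expect_equal(unname(res$df[["total"]]), n - 1)
  }
})

test_that("AMOVA sums of squares agree with an independent partitioner", {
  skip_if_not_installed("vegan")
  set.seed(10)
  aln <- random_alignment(18, 40)
  pops <- rep(c("A", "B", "C"), each = 6)
  d2 <- pairwise_difference_matrix(aln)
  res <- amova(d2, pops)
  # adonis2 squares its input distances, so feed sqrt(differences)
  adn <- vegan::adonis2(stats::as.dist(sqrt(d2)) ~ g,
                        data = data.frame(g = pops), permutations = 0)
  expect_equal(res$SS[["among_populations"]], adn$SumOfSqs[1],
               tolerance = 1e-9)
  expect_equal(res$SS[["within_populations"]], adn$SumOfSqs[2],
               tolerance = 1e-9)
})

test_that("fixed differences give Phi_ST = 1 with 100% among-population", {
  d2 <- matrix(1, 8, 8)
  d2[1:4, 1:4] <- 0
  d2[5:8, 5:8] <- 0
  diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- paste0("s", 1:8)
  res <- amova(d2, rep(c("A", "B"), each = 4))
  expect_equal(res$phi[["phi_ST"]], 1)
  expect_equal(unname(res$percent), c(100, 0))
})

test_that("panmictic pools give near-zero Phi_ST and calibrated p-values", {
  set.seed(3)
  sim <- simulate_coalescent(sim_config(c(30L), L = 300, theta = 3,
                                        seed = 33))
  d2 <- pairwise_difference_matrix(sim$alignment)
  pops <- rep(c("A", "B"), 15) # arbitrary split of one pool
  res <- amova(d2, pops, permutations = 200)
  expect_lt(abs(res$phi[["phi_ST"]]), 0.15)
  expect_gt(res$p_values[["phi_ST"]], 0.05)

  # permutation p-values approximately Uniform(0,1) under the null
  set.seed(14)
  aln <- random_alignment(16, 60, n_var = 20)
  d2n <- pairwise_difference_matrix(aln)
  ps <- replicate(200, {
    amova(d2n, sample(rep(c("A", "B"), 8)),
          permutations = 60)$p_values[["phi_ST"]]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise Phi_ST retains negative estimates and finds fixation", {
  d2 <- matrix(1, 8, 8)
  d2[1:4, 1:4] <- 0
  d2[5:8, 5:8] <- 0
  diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- paste0("s", 1:8)
  pw <- pairwise_phist(d2, rep(c("A", "B"), each = 4))
  expect_equal(pw$phi_st["A", "B"], 1)

  set.seed(8)
  sim <- simulate_coalescent(sim_config(c(24L), L = 250, theta = 3,
                                        seed = 44))
  d2n <- pairwise_difference_matrix(sim$alignment)
  pwn <- pairwise_phist(d2n, rep(c("X", "Y"), 12))
  expect_lt(abs(pwn$phi_st["X", "Y"]), 0.2) # may legitimately be negative
  expect_equal(diag(pwn$phi_st), c(X = 0, Y = 0))
})

test_that("two-level AMOVA degenerates consistently when groups = populations", {
  set.seed(5)
  aln <- random_alignment(12, 40)
  pops <- rep(c("A", "B", "C"), each = 4)
  d2 <- pairwise_difference_matrix(aln)
  one <- amova(d2, pops)
  two <- amova(d2, pops, groups = stats::setNames(c("gA", "gB", "gC"),
                                                  c("A", "B", "C")))
  expect_true(is.na(two$phi[["phi_SC"]]))
  expect_equal(two$phi[["phi_CT"]], one$phi[["phi_ST"]], tolerance = 1e-12)
})

test_that("SAMOVA annealing agrees with exhaustive enumeration", {
  set.seed(6)
  sim <- simulate_coalescent(sim_config(
    rep(8L, 7), L = 300, theta = 1.5, migration = 8,
    expansion = list(time = 1, fold = 50),
    diverged_deme = list(index = 7L, split_time = 5), seed = 55))
  d2 <- pairwise_difference_matrix(sim$alignment)
  pops <- unname(sim$popmap$assignments[sim$alignment$ids])
  for (K in c(2, 3)) {
    ex <- samova(d2, pops, K = K, seed = 1)
    an <- samova(d2, pops, K = K, exhaustive_limit = 0, n_starts = 20,
                 seed = 2)
    expect_equal(ex$method, "exhaustive")
    expect_equal(an$method, "annealing")
    expect_equal(an$phi_CT, ex$phi_CT, tolerance = 1e-9)
  }
})

test_that("SAMOVA isolates a strongly diverged deme at K=2", {
  set.seed(5)
  sim <- simulate_coalescent(sim_config(
    rep(10L, 4), L = 300, theta = 1.5, migration = 8,
    expansion = list(time = 1, fold = 50),
    diverged_deme = list(index = 4L, split_time = 6), seed = 5))
  d2 <- pairwise_difference_matrix(sim$alignment)
  pops <- unname(sim$popmap$assignments[sim$alignment$ids])
  res <- samova(d2, pops, K = 2, seed = 9)
  g_jn <- res$groups[["JNlike"]]
  others <- res$groups[setdiff(names(res$groups), "JNlike")]
  expect_false(g_jn %in% others)
  expect_equal(length(unique(others)), 1)
})
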
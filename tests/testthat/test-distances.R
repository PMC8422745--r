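test_that("K2P closed forms match hand evaluations", {
  expect_equal(k2p_distance("AAAA", "AAAA"), 0)
  # P = 0.1, Q = 0: -1/2 ln(0.8)
  a <- paste(rep(c("A", "G"), c(9, 1)), collapse = "")
  b <- paste(rep("A", 10), collapse = "")
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-9)
  expect_equal(k2p_distance(a, b), 0.11157, tolerance = 1e-4)
  # P = 0, Q = 0.1: -1/2 ln(0.9) - 1/4 ln(0.8)
  a2 <- paste(rep(c("A", "C"), c(9, 1)), collapse = "")
  expect_equal(k2p_distance(a2, b), -0.5 * log(0.9) - 0.25 * log(0.8),
               tolerance = 1e-9)
})

test_that("K2P agrees with an established implementation on random pairs", {
  set.seed(15)
  for (r in 1:5) {
    aln <- random_alignment(2, 60, n_var = 25)
    mine <- k2p_distance(paste(aln$seqs[1, ], collapse = ""),
                         paste(aln$seqs[2, ], collapse = ""))
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(aln$seqs)),
                                    model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("K2P correction never falls below the p-distance", {
  set.seed(16)
  for (r in 1:10) {
    aln <- random_alignment(2, 80, n_var = 30)
    p_dist <- mean(aln$seqs[1, ] != aln$seqs[2, ])
    if (p_dist == 0) next
    expect_gte(k2p_distance(paste(aln$seqs[1, ], collapse = ""),
                            paste(aln$seqs[2, ], collapse = "")), p_dist)
  }
  expect_error(
    k2p_distance(paste(rep(c("A", "G"), 5), collapse = ""),
                 paste(rep(c("G", "A"), 5), collapse = "")),
    "saturation")
})

test_that("between-population distances reduce to single-pair K2P", {
  # two monomorphic populations two transitions apart over 20 sites
  sA <- paste(rep("A", 20), collapse = "")
  sB <- paste(c(rep("A", 18), "G", "G"), collapse = "")
  aln <- new_alignment(paste0("s", 1:6), rep(c(sA, sB), each = 3))
  pm <- new_population_map(aln$ids, rep(c("X", "Y"), each = 3))
  ds <- between_population_distance(aln, pm)
  expect_equal(ds$between["X", "Y"], k2p_distance(sA, sB),
               tolerance = 1e-12)
  expect_equal(unname(ds$within), c(0, 0))

  # splitting one population in two: between ~ within
  set.seed(20)
  aln2 <- random_alignment(16, 50, n_var = 20)
  pm2 <- new_population_map(aln2$ids, rep(c("P", "Q"), 8))
  ds2 <- between_population_distance(aln2, pm2)
  expect_equal(ds2$between["P", "Q"], mean(ds2$within), tolerance = 0.3)
  # net distance subtracts the within-population means
  dsn <- between_population_distance(aln2, pm2, net = TRUE)
  expect_equal(dsn$between["P", "Q"],
               ds2$between["P", "Q"] - mean(ds2$within), tolerance = 1e-12)
})

test_that("UPGMA reproduces the hand-worked three-taxon clustering", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(dm)
  coph <- stats::cophenetic(tr)
  # heights d/2: A-B merge at 1, root at 2 -> cophenetic reproduces dm
  expect_equal(coph[rownames(dm), colnames(dm)], dm, tolerance = 1e-12)
})

test_that("UPGMA trees are ultrametric", {
  set.seed(30)
  aln <- random_alignment(12, 60, n_var = 25)
  pm <- new_population_map(aln$ids, rep(c("A", "B", "C", "D"), each = 3))
  ds <- between_population_distance(aln, pm)
  tr <- upgma_tree(ds$between)
  depth <- ape::node.depth.edgelength(tr)
  tip_depth <- depth[seq_along(tr$tip.label)]
  expect_lt(max(tip_depth) - min(tip_depth), 1e-9)
})

test_that("NJ recovers additive four-taxon trees exactly", {
  # known tree: ((A:1,B:2):1,(C:3,D:1):2) as an unrooted metric
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 1 + 1 + 2 + 3
  dm["A", "D"] <- dm["D", "A"] <- 1 + 1 + 2 + 1
  dm["B", "C"] <- dm["C", "B"] <- 2 + 1 + 2 + 3
  dm["B", "D"] <- dm["D", "B"] <- 2 + 1 + 2 + 1
  dm["C", "D"] <- dm["D", "C"] <- 4
  tr <- nj_tree(dm)
  coph <- stats::cophenetic(tr)
  expect_equal(coph[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  # AB | CD split present
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
})

test_that("tree construction is deterministic and validates input", {
  dm <- sinensis_ds_matrix()
  t1 <- ape::write.tree(upgma_tree(dm))
  t2 <- ape::write.tree(upgma_tree(dm))
  expect_identical(t1, t2)
  bad <- dm
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(upgma_tree(bad), "symmetric")
})
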
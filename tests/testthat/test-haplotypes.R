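test_that("identical sequences collapse to a single haplotype", {
  aln <- new_alignment(paste0("s", 1:4), rep("ACGTACGT", 4))
  ht <- collapse_haplotypes(aln)
  expect_equal(length(ht$haplotype_id), 1)
  expect_equal(unname(ht$counts[1, 1]), 4)
})

test_that("haplotype ids rank by frequency with the modal type first", {
  aln <- new_alignment(c("x", "y", "z"), c("AAA", "AAT", "AAT"))
  ht <- collapse_haplotypes(aln)
  expect_equal(ht$haplotype_id, c("Hap_1", "Hap_2"))
  expect_equal(ht$sequence[1], "AAT")
  expect_equal(unname(rowSums(ht$counts)), c(2, 1))
})

test_that("per-population counts conserve sample sizes", {
  set.seed(42)
  aln <- random_alignment(30, 40)
  pm <- new_population_map(aln$ids, rep(c("A", "B", "C"), each = 10))
  ht <- collapse_haplotypes(aln, pm)
  expect_equal(unname(colSums(ht$counts)), c(10, 10, 10))
  expect_equal(sum(ht$counts), ht$total_n)
  expect_true(all(rowSums(ht$counts) >= 1))
})

test_that("collapsing is idempotent under expansion by counts", {
  set.seed(7)
  aln <- random_alignment(25, 30)
  pm <- new_population_map(aln$ids, rep(c("A", "B"), c(12, 13)))
  ht <- collapse_haplotypes(aln, pm)
  ex <- expand_haplotype_table(ht)
  ht2 <- collapse_haplotypes(ex$alignment, ex$popmap)
  expect_equal(ht2$sequence, ht$sequence)
  expect_equal(unname(ht2$counts[, colnames(ht$counts)]),
               unname(ht$counts))
})

test_that("site summary follows the segregating/informative definitions", {
  mono <- new_alignment(paste0("s", 1:5), rep("ACGT", 5))
  expect_equal(site_summary(mono)$S, 0)

  # column 1: A,A,T,T informative; column 2: A,A,A,T singleton
  aln <- new_alignment(paste0("s", 1:4), c("AA", "AA", "TA", "TT"))
  ss <- site_summary(aln)
  expect_equal(ss$S, 2)
  expect_equal(ss$parsimony_informative, 1)
  expect_equal(ss$singleton_sites, 1)
  expect_equal(ss$parsimony_informative + ss$singleton_sites, ss$S)
})

test_that("site summary is invariant to sequence order", {
  set.seed(3)
  aln <- random_alignment(12, 25)
  perm <- sample(length(aln$ids))
  shuffled <- new_alignment(aln$ids[perm],
                            apply(aln$seqs[perm, ], 1, paste,
                                  collapse = ""))
  expect_equal(site_summary(shuffled), site_summary(aln))
})

test_that("columns with missing data are excluded by complete deletion", {
  aln <- new_alignment(c("a", "b", "c"), c("AC-TA", "ACGTA", "NCGTT"))
  expect_equal(included_sites(aln), c(2, 4, 5))
  ht <- collapse_haplotypes(aln)
  expect_equal(ht$excluded_sites, 2)
  # a and b identical on included sites -> one haplotype
  expect_equal(length(ht$haplotype_id), 2)
  expect_equal(site_summary(aln)$excluded_sites, 2)
})

test_that("shared and unique haplotype counts behave at the boundaries", {
  one <- collapse_haplotypes(new_alignment(c("a", "b"), c("AAA", "ATA")))
  su <- shared_and_unique(one)
  expect_equal(su$per_population$h, su$per_population$h_prime)

  two <- new_alignment(paste0("s", 1:4), c("AAA", "AAA", "TTT", "TTT"))
  pm <- new_population_map(two$ids, c("X", "X", "Y", "Y"))
  su2 <- shared_and_unique(collapse_haplotypes(two, pm))
  expect_equal(su2$n_shared, 0)
  expect_equal(su2$per_population$h_prime, c(1, 1))
})

test_that("haplotype tables round-trip through CSV", {
  set.seed(9)
  aln <- random_alignment(15, 20)
  pm <- new_population_map(aln$ids, rep(c("A", "B", "C"), each = 5))
  ht <- collapse_haplotypes(aln, pm)
  p <- tempfile(fileext = ".csv")
  write_haplotype_table(ht, p)
  back <- read_haplotype_table(p)
  expect_equal(back$haplotype_id, ht$haplotype_id)
  expect_equal(unname(back$counts), unname(ht$counts))
  ex <- expand_haplotype_table(back)
  expect_equal(length(ex$alignment$ids), ht$total_n)
})
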
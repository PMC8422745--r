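test_that("mismatch histograms count pairwise differences correctly", {
  same <- new_alignment(c("a", "b", "c"), rep("ACGTACGT", 3))
  h <- mismatch_histogram(same)
  expect_equal(unname(h), 1)
  expect_equal(names(h), "0")

  # three sequences at mutual distances 1, 1, 2
  aln <- new_alignment(c("a", "b", "c"), c("AAAA", "AAAT", "AATA"))
  h2 <- mismatch_histogram(aln)
  expect_equal(unname(h2), c(0, 2 / 3, 1 / 3))
  expect_error(mismatch_histogram(new_alignment("a", "ACGT")), "n >= 2")
})

test_that("expected mismatch reduces to the equilibrium geometric at tau=0", {
  for (theta in c(0.2, 1, 5, 40)) {
    i <- 0:30
    expect_equal(expected_mismatch(0, theta, theta, i),
                 theta^i / (1 + theta)^(i + 1), tolerance = 1e-12)
  }
  expect_equal(expected_mismatch(0, 1, 1, 0:1), c(0.5, 0.25),
               tolerance = 1e-12)
  # tau=0, theta -> 0: all mass at class 0
  expect_equal(expected_mismatch(0, 0, 0, 0:5), c(1, 0, 0, 0, 0, 0))
})

test_that("expected mismatch normalizes over its infinite support", {
  for (par in list(c(0, 1, 1), c(4, 0.5, 60), c(10, 0, 99999),
                   c(2.5, 1.5, 8))) {
    expect_equal(sum(expected_mismatch(par[1], par[2], par[3], 0:500)), 1,
                 tolerance = 1e-6)
  }
})

test_that("sudden-expansion fitting recovers exact model parameters", {
  obs <- expected_mismatch(2, 0.5, 50, 0:40)
  obs <- obs / sum(obs)
  fit <- fit_sudden_expansion(obs)
  expect_lt(fit$SSD, 1e-8)
  expect_equal(fit$tau, 2, tolerance = 0.05)
  expect_equal(fit$theta0, 0.5, tolerance = 0.05)
  expect_equal(fit$theta1, 50, tolerance = 0.05 * 50)
})

test_that("degenerate single-class data yield the tau=0 fit", {
  expect_warning(fit <- fit_sudden_expansion(c(1)), "degenerate")
  expect_equal(fit$tau, 0)
  expect_equal(fit$SSD, 0, tolerance = 1e-12)
})

test_that("theta1 reports at its cap for star-like expansion signals", {
  # expansion with effectively infinite post-expansion size
  obs <- expected_mismatch(3, 0, 99999, 0:25)
  obs <- obs / sum(obs)
  fit <- fit_sudden_expansion(obs)
  expect_equal(fit$theta1, 99999)
  expect_equal(fit$tau, 3, tolerance = 0.1)
})

test_that("raggedness follows the zero-padded squared-step definition", {
  # flat two-class distribution: interior step contributes 0
  expect_equal(harpending_raggedness(c(0.5, 0.5)), 0.25)
  x <- c(0.2, 0.5, 0.3)
  expect_equal(harpending_raggedness(x),
               (0.5 - 0.2)^2 + (0.3 - 0.5)^2 + (0 - 0.3)^2)
})

test_that("goodness-of-fit p-values are calibrated under the true model", {
  set.seed(7)
  ps <- replicate(30, {
    obs <- simulate_mismatch(16, 2, 0.3, 30)
    fit <- suppressWarnings(fit_sudden_expansion(obs))
    goodness_of_fit(obs, fit, n = 16, reps = 100)$SSD_p
  })
  # under the fitted model SSD_p should not pile up near 0
  expect_gt(mean(ps > 0.05), 0.7)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("expansion time conversion is exact and linear in tau", {
  cl <- mutation_clock()
  expect_equal(expansion_time(0, cl)$t_years, 0)
  expect_equal(expansion_time(2, cl)$t_years,
               2 * expansion_time(1, cl)$t_years, tolerance = 1e-12)
  expect_equal(cl$mu, 1.5 * 674 * 1.4e-8, tolerance = 1e-15)
  expect_error(mutation_clock(rate_per_site_per_year = 0), "positive")
  expect_error(expansion_time(-1, cl), "tau")
})

test_that("mismatch table runs per population with expansion times", {
  set.seed(21)
  sim <- simulate_coalescent(sim_config(c(10L, 10L), L = 300, theta = 2,
                                        expansion = list(time = 1,
                                                         fold = 50),
                                        migration = 4, seed = 77))
  mt <- mismatch_table(sim$alignment, sim$popmap, reps = 100, seed = 3)
  expect_equal(nrow(mt$table), 3)
  expect_true(all(mt$table$tau >= 0))
  expect_true(all(mt$table$theta0 <= mt$table$theta1))
  expect_equal(mt$table$t_years, mt$table$t_Ma * 1e6)
  expect_equal(length(mt$histograms), 3)
})
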
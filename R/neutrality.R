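# Neutrality tests: Tajima's D and Fu's Fs, with coalescent-simulation
# p-values (lower tail, as in the standard Arlequin-style workflow).

#' Tajima's D statistic
#'
#' `D = (K - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the Tajima (1989)
#' constants `a1, a2, b1, b2, c1, c2, e1, e2`.
#'
#' @param n Sample size (number of sequences), `n >= 4`.
#' @param S Number of segregating sites.
#' @param K Mean pairwise difference count.
#' @return `D`, or `NA` (with a warning) when `S = 0`, where the statistic
#'   is undefined.
#' @export
tajimas_d <- function(n, S, K) {
  if (n < 4) stop("Tajima's D needs n >= 4")
  if (S == 0) {
    warning("Tajima's D undefined for S = 0")
    return(NA_real_)
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n:
# returns log|s(n,k)| for k = 1..n (log-space recurrence, stable to n of
# several hundred where the raw numbers overflow doubles)
log_stirling1 <- function(n) {
  ls <- 0 # row 1: |s(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in 2:n) {
    prev <- c(-Inf, ls, -Inf) # pad k = 0 and k = m
    ls <- vapply(seq_len(m), function(k) {
      a <- log(m - 1) + prev[k + 1L] # (m-1) * |s(m-1, k)|
      b <- prev[k]                   # |s(m-1, k-1)|
      mx <- max(a, b)
      if (is.infinite(mx)) -Inf else mx + log(exp(a - mx) + exp(b - mx))
    }, numeric(1L))
  }
  ls
}

#' Ewens sampling distribution of the number of alleles
#'
#' `Pr(K = k) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1))` for
#' `k = 1..n`, computed in log space.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @return Numeric vector of probabilities for `k = 1..n` (sums to 1).
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) stop("theta must be > 0")
  k <- seq_len(n)
  logp <- log_stirling1(n) + k * log(theta) -
    sum(log(theta + 0:(n - 1)))
  exp(logp)
}

#' Fu's Fs statistic
#'
#' `S' = Pr(K >= k_obs | theta, n)` under the Ewens sampling distribution
#' with `theta` the pairwise estimate (mean pairwise differences), and
#' `Fs = ln(S' / (1 - S'))`. Strongly negative values indicate an excess of
#' rare haplotypes, as after a demographic expansion.
#'
#' @param n Sample size (`>= 2`).
#' @param theta Driving theta (pairwise estimate `K`), `> 0`.
#' @param k_obs Observed number of distinct haplotypes (`>= 1`).
#' @return `Fs` (possibly `Inf`/`-Inf` with a warning at the numerical
#'   boundaries `S'` of 1 or 0).
#' @export
fus_fs <- function(n, theta, k_obs) {
  if (n < 2) stop("Fu's Fs needs n >= 2")
  if (k_obs < 1) stop("k_obs must be >= 1")
  if (theta <= 0) stop("theta must be > 0 (monomorphic sample: Fs undefined)")
  if (k_obs == 1L) {
    warning("k_obs = 1: S' = 1, Fs undefined-high (+Inf)")
    return(Inf)
  }
  k <- seq_len(n)
  logp <- log_stirling1(n) + k * log(theta) - sum(log(theta + 0:(n - 1)))
  lse <- function(x) {
    m <- max(x)
    if (is.infinite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
  log_upper <- lse(logp[k >= k_obs])
  log_lower <- lse(logp[k < k_obs])
  if (is.infinite(log_upper)) {
    warning("S' underflows to 0; Fs reported as -Inf")
    return(-Inf)
  }
  if (is.infinite(log_lower)) {
    warning("S' numerically 1; Fs reported as +Inf")
    return(Inf)
  }
  log_upper - log_lower
}

#' Coalescent-simulation p-value for a neutrality statistic
#'
#' Neutral constant-size coalescent samples of size `n` are generated
#' conditional on the observed estimate: for `D`, the observed number of
#' segregating sites is dropped on the genealogy (fixed-S scheme); for
#' `Fs`, mutations are Poisson with the pairwise theta estimate. The
#' p-value is the fraction of simulated statistics less than or equal to
#' the observed one (lower tail). For `Fs` the customary significance
#' threshold is 0.02 for a test at the nominal 5% level; the raw p is
#' returned.
#'
#' @param n Sample size.
#' @param S_or_theta Observed `S` (for `statistic = "D"`) or pairwise theta
#'   (for `"Fs"`).
#' @param observed Observed statistic value.
#' @param statistic `"D"` or `"Fs"`.
#' @param reps Number of coalescent replicates (>= 100).
#' @param seed Optional integer seed (set for reproducibility).
#' @return List with `p`, `null` (simulated statistics) and `reps`.
#' @export
neutrality_pvalue <- function(n, S_or_theta, observed,
                              statistic = c("D", "Fs"),
                              reps = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.na(observed)) return(list(p = NA_real_, null = numeric(0),
                                   reps = reps))
  null <- vapply(seq_len(reps), function(r) {
    g <- sim_genealogy(n)
    if (statistic == "D") {
      m <- branch_mutations(g, S = S_or_theta)
      st <- genealogy_stats(g, m)
      tajimas_d(n, st$S, st$K)
    } else {
      m <- branch_mutations(g, theta = S_or_theta)
      st <- genealogy_stats(g, m)
      if (st$K <= 0 || st$k_obs == 1L) NA_real_ else
        suppressWarnings(fus_fs(n, st$K, st$k_obs))
    }
  }, numeric(1L))
  # monomorphic or boundary replicates carry no information for the tail
  null <- null[is.finite(null)]
  list(p = mean(null <= observed), null = null, reps = reps)
}

#' Neutrality-test table for every population (plus pooled)
#'
#' @param aln A `coi_alignment`.
#' @param pm A `coi_popmap`.
#' @param reps Coalescent replicates per p-value.
#' @param seed Integer seed.
#' @param pooled_label Label for the pooled row.
#' @return data.frame with Population, n, S, K, k_obs, D, D_p, Fs, Fs_p.
#' @export
neutrality_table <- function(aln, pm, reps = 10000, seed = 1,
                             pooled_label = "Pooled") {
  pops <- pop_labels(aln, pm)
  one <- function(sub, label) {
    ss <- site_summary(sub)
    nd <- nucleotide_diversity(sub)
    ht <- collapse_haplotypes(sub)
    k_obs <- length(ht$haplotype_id)
    D <- if (ss$S >= 1) tajimas_d(nd$n, ss$S, nd$K) else NA_real_
    Fs <- if (nd$K > 0) fus_fs(nd$n, nd$K, k_obs) else NA_real_
    D_p <- if (!is.na(D)) {
      neutrality_pvalue(nd$n, ss$S, D, "D", reps = reps)$p
    } else NA_real_
    Fs_p <- if (!is.na(Fs) && is.finite(Fs)) {
      neutrality_pvalue(nd$n, nd$K, Fs, "Fs", reps = reps)$p
    } else NA_real_
    data.frame(Population = label, n = nd$n, S = ss$S, K = nd$K,
               k_obs = k_obs, D = D, D_p = D_p, Fs = Fs, Fs_p = Fs_p,
               stringsAsFactors = FALSE)
  }
  set.seed(seed)
  rows <- lapply(unique(pops), function(p) {
    one(subset_alignment(aln, pops == p), p)
  })
  rbind(do.call(rbind, rows), one(aln, pooled_label))
}
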
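# Independent oracles and fixture builders used across the suite. Every
# oracle is a deliberately naive implementation (explicit loops,
# enumeration) kept separate from the package's computation paths.

# random equal-length alignment with controllable diversity
random_alignment <- function(n, L, n_var = max(2L, L %/% 5L)) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    var_sites <- seq_len(n_var)
    flip <- var_sites[stats::runif(n_var) < 0.3]
    for (j in flip) s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1L)
    paste(s, collapse = "")
  }, character(1L))
  new_alignment(paste0("s", seq_len(n)), seqs)
}

# brute-force haplotype diversity: probability two distinct draws differ
brute_hd <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  same <- sum(counts * (counts - 1))
  1 - same / (n * (n - 1))
}

# brute-force K and pi by an explicit double loop over all pairs
brute_pi_k <- function(seqmat) {
  n <- nrow(seqmat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(seqmat[i, ] != seqmat[j, ])
  }
  K <- tot / (n * (n - 1) / 2)
  list(K = K, pi = K / ncol(seqmat))
}

# exact Ewens distribution of the allele count by enumerating integer
# partitions of n (feasible for n <= 8): Pr(config a) =
# n! / theta_(n) * prod_j (theta/j)^a_j / a_j!
ewens_k_oracle <- function(n, theta) {
  parts <- integer_partitions(n)
  pk <- numeric(n)
  rising <- prod(theta + 0:(n - 1))
  for (p in parts) {
    a <- tabulate(p, n)
    k <- length(p)
    prob <- factorial(n) / rising *
      prod((theta / seq_len(n))^a / factorial(a))
    pk[k] <- pk[k] + prob
  }
  pk
}

integer_partitions <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

# one-level AMOVA variance components transcribed directly from the
# expected-mean-square equations, explicit loops throughout
amova_oracle_onelevel <- function(d2, pops) {
  labs <- unique(pops)
  N <- length(pops)
  P <- length(labs)
  sstot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sstot <- sstot + d2[i, j]
  sstot <- sstot / N
  ssw <- 0
  for (p in labs) {
    ix <- which(pops == p)
    acc <- 0
    for (i in ix) for (j in ix) if (i < j) acc <- acc + d2[i, j]
    ssw <- ssw + acc / length(ix)
  }
  ssa <- sstot - ssw
  n_p <- sapply(labs, function(p) sum(pops == p))
  sig_w <- ssw / (N - P)
  nprime <- (N - sum(n_p^2) / N) / (P - 1)
  sig_a <- (ssa / (P - 1) - sig_w) / nprime
  list(SS = c(among = ssa, within = ssw, total = sstot),
       sigma = c(among = sig_a, within = sig_w),
       phi_ST = sig_a / (sig_a + sig_w))
}

# Monte-Carlo oracle for the parsimony probability: j mutations placed
# uniformly on m sites, probability all strike distinct sites
parsimony_prob_mc <- function(j, m, reps = 20000) {
  hits <- replicate(reps, {
    sites <- sample.int(m, j, replace = TRUE)
    length(unique(sites)) == j
  })
  mean(hits)
}

# small deterministic alignment shared by several io/haplotype tests
tiny_alignment <- function() {
  new_alignment(c("a1", "a2", "a3", "a4"),
                c("AATGC", "AATGC", "AATGA", "AGTGA"))
}

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
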
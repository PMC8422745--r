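# Haploid structured-coalescent engine.
#
# Time runs backward in units of N0 generations for a reference deme size
# N0 (mtDNA: number of females). A pair of lineages in a deme of relative
# size sigma coalesces at rate 1/sigma; each lineage in the migration set
# moves at rate M/2 to a uniformly chosen other deme of that set
# (island model, M = 2*N0*m); mutations are later placed on branches at
# rate theta/2 per unit time per lineage (theta = 2*N0*u for a whole-locus
# per-generation mutation rate u), so a constant-size deme has expected
# pairwise difference theta and expected segregating sites theta*a1.
#
# Supported demography: sudden expansion (all demes were sigma/fold before
# time `expansion$time`) and one diverged deme excluded from migration that
# joins another deme at `join$time`. All randomness uses R's RNG (Mersenne
# Twister), so runs are reproducible under set.seed().

# returns list(parent, node_time, n, leaf_deme); nodes 1..n are leaves,
# parent index always exceeds child index, root has parent 0
sim_genealogy <- function(sample_sizes,
                          deme_sizes = rep(1, length(sample_sizes)),
                          expansion = NULL, join = NULL,
                          migration = 0, migration_demes = NULL) {
  d <- length(sample_sizes)
  n <- sum(sample_sizes)
  if (n < 2) stop("need at least 2 sampled lineages")
  ntot <- 2L * n - 1L
  parent <- integer(ntot)
  node_time <- numeric(ntot)
  act <- seq_len(n)
  deme <- rep(seq_len(d), sample_sizes)
  leaf_deme <- deme
  if (is.null(migration_demes)) migration_demes <- seq_len(d)
  if (!is.null(join)) migration_demes <- setdiff(migration_demes, join$from)
  bounds <- sort(unique(c(
    if (!is.null(expansion)) expansion$time,
    if (!is.null(join)) join$time)))
  t <- 0
  nxt <- n
  # `act` (node ids) and `deme` (deme of each active lineage) are kept
  # parallel by position throughout
  repeat {
    if (length(act) == 1L) break
    sz <- deme_sizes
    if (!is.null(expansion) && t >= expansion$time) sz <- sz / expansion$fold
    k <- tabulate(deme, d)
    coal <- k * (k - 1) / 2 / sz
    n_mig <- if (length(migration_demes) > 1L) {
      sum(deme %in% migration_demes)
    } else 0L
    mig <- migration / 2 * n_mig
    tot <- sum(coal) + mig
    nb <- bounds[bounds > t]
    if (tot <= 0) {
      if (length(nb) == 0L) {
        stop("lineages cannot coalesce: zero total event rate")
      }
      t <- nb[1L]
    } else {
      dt <- stats::rexp(1L, tot)
      if (length(nb) > 0L && t + dt > nb[1L]) {
        t <- nb[1L]
      } else {
        t <- t + dt
        if (stats::runif(1L) < sum(coal) / tot) {
          dm <- sample.int(d, 1L, prob = coal)
          pos_dm <- which(deme == dm)
          pos <- if (length(pos_dm) == 2L) pos_dm else
            pos_dm[sample.int(length(pos_dm), 2L)]
          nxt <- nxt + 1L
          parent[act[pos]] <- nxt
          node_time[nxt] <- t
          act <- c(act[-pos], nxt)
          deme <- c(deme[-pos], dm)
          next
        } else {
          idx <- which(deme %in% migration_demes)
          who <- idx[sample.int(length(idx), 1L)]
          dest <- setdiff(migration_demes, deme[who])
          deme[who] <- dest[sample.int(length(dest), 1L)]
          next
        }
      }
    }
    # boundary reached: apply join once, epoch sizes update implicitly
    if (!is.null(join) && t == join$time) {
      deme[deme == join$from] <- join$to
      migration_demes <- union(migration_demes, join$to)
      join <- NULL
    }
  }
  list(parent = parent, node_time = node_time, n = n,
       leaf_deme = leaf_deme)
}

# leaves below each node
subtree_sizes <- function(g) {
  ntot <- length(g$parent)
  sz <- c(rep(1L, g$n), integer(ntot - g$n))
  for (v in seq_len(ntot - 1L)) sz[g$parent[v]] <- sz[g$parent[v]] + sz[v]
  sz
}

branch_lengths <- function(g) {
  ntot <- length(g$parent)
  len <- numeric(ntot)
  v <- seq_len(ntot - 1L)
  len[v] <- g$node_time[g$parent[v]] - g$node_time[v]
  len
}

# mutation counts per branch: fixed total S (multinomial on lengths) or
# Poisson with rate theta/2 per unit length
branch_mutations <- function(g, S = NULL, theta = NULL) {
  len <- branch_lengths(g)
  ntot <- length(len)
  m <- integer(ntot)
  idx <- seq_len(ntot - 1L)
  if (!is.null(S)) {
    if (S > 0L) {
      m[idx] <- as.integer(stats::rmultinom(1L, S, prob = len[idx]))
    }
  } else {
    m[idx] <- stats::rpois(ntot - 1L, theta / 2 * len[idx])
  }
  m
}

# S, K (mean pairwise differences) and k_obs (distinct infinite-sites
# haplotypes) implied by per-branch mutation counts
genealogy_stats <- function(g, m) {
  sz <- subtree_sizes(g)
  n <- g$n
  ntot <- length(g$parent)
  idx <- seq_len(ntot - 1L)
  K <- sum(m[idx] * sz[idx] * (n - sz[idx])) / choose(n, 2)
  grp <- integer(ntot)
  grp[ntot] <- 1L
  nid <- 1L
  for (v in (ntot - 1L):1L) {
    if (m[v] > 0L) {
      nid <- nid + 1L
      grp[v] <- nid
    } else {
      grp[v] <- grp[g$parent[v]]
    }
  }
  list(S = sum(m), K = K, k_obs = length(unique(grp[seq_len(n)])))
}

# per-pair difference counts (infinite sites) as an n x n matrix
genealogy_pairdiffs <- function(g, m) {
  ntot <- length(g$parent)
  n <- g$n
  below <- vector("list", ntot)
  for (v in seq_len(n)) below[[v]] <- v
  d <- matrix(0, n, n)
  for (v in seq_len(ntot - 1L)) {
    p <- g$parent[v]
    if (m[v] > 0L) {
      ins <- below[[v]]
      outs <- setdiff(seq_len(n), ins)
      d[ins, outs] <- d[ins, outs] + m[v]
    }
    below[[p]] <- c(below[[p]], below[[v]])
  }
  # d was filled one-sidedly per branch; fold to a symmetric matrix
  d + t(d)
}

# finite-sites sequences: root drawn uniformly, each mutation hits a
# uniform site; transitions (A<->G, C<->T) chosen with probability
# tstv/(tstv+1), else one of the two transversions
genealogy_sequences <- function(g, m, L, tstv = 10) {
  ntot <- length(g$parent)
  n <- g$n
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  seqs <- matrix(NA_character_, ntot, L)
  seqs[ntot, ] <- sample(bases, L, replace = TRUE)
  for (v in (ntot - 1L):1L) {
    s <- seqs[g$parent[v], ]
    if (m[v] > 0L) {
      for (mu in seq_len(m[v])) {
        site <- sample.int(L, 1L)
        cur <- s[site]
        if (stats::runif(1L) < tstv / (tstv + 1)) {
          s[site] <- ts_partner[[cur]]
        } else {
          s[site] <- sample(setdiff(bases, c(cur, ts_partner[[cur]])), 1L)
        }
      }
    }
    seqs[v, ] <- s
  }
  seqs[seq_len(n), , drop = FALSE]
}
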
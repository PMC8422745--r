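# Analysis of molecular variance (Excoffier-Smouse-Quattro) on pairwise
# sequence differences, Phi-statistics with permutation tests, and a
# SAMOVA-style search for the population grouping that maximizes the
# among-group index Phi_CT.
#
# Following the Arlequin convention for haplotype data, the "distance"
# entering the sums of squares is the pairwise difference count itself
# (used as a squared Euclidean distance), so the indices are
# Phi-statistics even when reported under the FST label.

#' Pairwise difference matrix between all samples
#'
#' Number of differing included (complete-deletion) sites per sequence
#' pair.
#'
#' @param aln A `coi_alignment`.
#' @return Symmetric integer matrix with sample ids as dimnames.
#' @export
pairwise_difference_matrix <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  inc <- included_sites(aln)
  pairdiff_matrix(aln$seqs[, inc, drop = FALSE])
}

# sum of squares of a set of samples: (1/n) * sum_{i<j} delta2_ij
ss_within <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sum(d2[idx, idx]) / 2 / length(idx)
}

# core variance decomposition; groups = named list(population -> group id)
amova_components <- function(d2, pops, group_of = NULL) {
  pop_levels <- unique(pops)
  P <- length(pop_levels)
  N <- length(pops)
  idx_of <- lapply(pop_levels, function(p) which(pops == p))
  names(idx_of) <- pop_levels
  n_p <- lengths(idx_of)
  if (any(n_p < 2L)) {
    stop("population with fewer than 2 samples: ",
         paste(pop_levels[n_p < 2L], collapse = ", "))
  }
  ss_tot <- ss_within(d2, seq_len(N))
  ss_wp <- sum(vapply(idx_of, function(ix) ss_within(d2, ix), numeric(1L)))
  if (is.null(group_of)) {
    # one-level design
    df_a <- P - 1L
    df_w <- N - P
    ss_a <- ss_tot - ss_wp
    ms_a <- ss_a / df_a
    sig_w <- ss_wp / df_w
    n_prime <- (N - sum(n_p^2) / N) / df_a
    sig_a <- (ms_a - sig_w) / n_prime
    tot <- sig_a + sig_w
    return(list(
      design = "one-level",
      df = c(among_populations = df_a, within_populations = df_w,
             total = N - 1L),
      SS = c(among_populations = ss_a, within_populations = ss_wp,
             total = ss_tot),
      sigma = c(among_populations = sig_a, within_populations = sig_w),
      percent = 100 * c(among_populations = sig_a, within_populations =
                          sig_w) / tot,
      phi = c(phi_ST = sig_a / tot)
    ))
  }
  grp <- group_of[pops]
  grp_levels <- unique(group_of[pop_levels])
  G <- length(grp_levels)
  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P
  idx_g <- lapply(grp_levels, function(g) which(grp == g))
  ss_wg <- sum(vapply(idx_g, function(ix) ss_within(d2, ix), numeric(1L)))
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp
  sig_c <- ss_wp / df_wp
  n_g <- lengths(idx_g)
  # coefficients of the expected mean squares (Excoffier et al. 1992)
  sum_np2_over_ng <- sum(vapply(grp_levels, function(g) {
    pops_in_g <- pop_levels[group_of[pop_levels] == g]
    sum(n_p[pops_in_g]^2) / sum(n_p[pops_in_g])
  }, numeric(1L)))
  n1 <- (N - sum_np2_over_ng) / df_ap
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  sig_b <- if (df_ap > 0L) (ss_ap / df_ap - sig_c) / n1 else NA_real_
  ms_ag <- ss_ag / df_ag
  sig_a <- (ms_ag - sig_c - n2 * ifelse(is.na(sig_b), 0, sig_b)) / n3
  tot <- sig_a + ifelse(is.na(sig_b), 0, sig_b) + sig_c
  list(
    design = "two-level",
    df = c(among_groups = df_ag, among_populations_within_groups = df_ap,
           within_populations = df_wp, total = N - 1L),
    SS = c(among_groups = ss_ag, among_populations_within_groups = ss_ap,
           within_populations = ss_wp, total = ss_tot),
    sigma = c(among_groups = sig_a,
              among_populations_within_groups = sig_b,
              within_populations = sig_c),
    percent = 100 * c(among_groups = sig_a,
                      among_populations_within_groups =
                        ifelse(is.na(sig_b), 0, sig_b),
                      within_populations = sig_c) / tot,
    phi = c(phi_CT = sig_a / tot,
            phi_SC = if (is.na(sig_b)) NA_real_ else sig_b /
              (sig_b + sig_c),
            phi_ST = (sig_a + ifelse(is.na(sig_b), 0, sig_b)) / tot)
  )
}

#' Analysis of molecular variance
#'
#' One-level (among/within populations) or, when `groups` is given,
#' two-level (among groups / among populations within groups / within
#' populations) AMOVA from a matrix of pairwise sequence differences, with
#' permutation p-values: samples among populations for `phi_ST`
#' (one-level), whole populations among groups for `phi_CT`, and samples
#' among populations within groups for `phi_SC`.
#'
#' @param d2 Sample-by-sample pairwise difference matrix (from
#'   [pairwise_difference_matrix()]).
#' @param pops Character vector of population labels per sample (or a
#'   `coi_popmap` together with dimnames on `d2`).
#' @param groups Optional named vector mapping population label -> group
#'   label (two-level design).
#' @param permutations Number of permutations (0 = no p-values).
#' @param seed Optional integer seed.
#' @return A `coi_amova`: the variance decomposition plus `p_values`.
#' @export
amova <- function(d2, pops, groups = NULL, permutations = 0, seed = NULL) {
  if (inherits(pops, "coi_popmap")) {
    pops <- unname(pops$assignments[rownames(d2)])
  }
  stopifnot(nrow(d2) == length(pops))
  if (length(unique(pops)) < 2L) stop("AMOVA needs at least 2 populations")
  if (!is.null(seed)) set.seed(seed)
  res <- amova_components(d2, pops, groups)
  pv <- c()
  if (permutations > 0) {
    if (is.null(groups)) {
      null_st <- vapply(seq_len(permutations), function(r) {
        amova_components(d2, sample(pops))$phi[["phi_ST"]]
      }, numeric(1L))
      pv <- c(phi_ST = mean(null_st >= res$phi[["phi_ST"]]))
    } else {
      pop_levels <- unique(pops)
      # phi_CT: permute whole populations among groups
      glab <- groups[pop_levels]
      null_ct <- vapply(seq_len(permutations), function(r) {
        g2 <- stats::setNames(sample(glab), pop_levels)
        amova_components(d2, pops, g2)$phi[["phi_CT"]]
      }, numeric(1L))
      # phi_SC: permute samples among populations within groups
      null_sc <- vapply(seq_len(permutations), function(r) {
        p2 <- pops
        for (g in unique(groups)) {
          in_g <- which(groups[pops] == g)
          p2[in_g] <- sample(pops[in_g])
        }
        amova_components(d2, p2, groups)$phi[["phi_SC"]]
      }, numeric(1L))
      # phi_ST: permute samples among populations ignoring groups
      null_st <- vapply(seq_len(permutations), function(r) {
        amova_components(d2, sample(pops), groups)$phi[["phi_ST"]]
      }, numeric(1L))
      pv <- c(phi_CT = mean(null_ct >= res$phi[["phi_CT"]]),
              phi_SC = mean(null_sc >= res$phi[["phi_SC"]],
                            na.rm = TRUE),
              phi_ST = mean(null_st >= res$phi[["phi_ST"]]))
    }
  }
  structure(c(res, list(p_values = pv, permutations = permutations,
                        groups = groups)),
            class = "coi_amova")
}

#' @export
print.coi_amova <- function(x, ...) {
  cat("<coi_amova> ", x$design, " design\n", sep = "")
  df <- data.frame(df = x$df[names(x$SS)], SS = x$SS,
                   sigma = c(x$sigma, NA)[seq_along(x$SS)],
                   percent = c(x$percent, NA)[seq_along(x$SS)])
  print(round(df, 4))
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), collapse = "  "), "\n")
  if (length(x$p_values)) {
    cat("p:  ", paste(names(x$p_values), round(x$p_values, 4),
                      collapse = "  "), "\n")
  }
  invisible(x)
}

#' Pairwise Phi_ST matrix with permutation p-values
#'
#' Each population pair is analyzed as a two-population one-level AMOVA.
#' Negative estimates are retained (not clamped to zero).
#'
#' @inheritParams amova
#' @return List with `phi_st` (symmetric matrix) and `p_values` (matrix,
#'   `NA` when `permutations = 0`).
#' @export
pairwise_phist <- function(d2, pops, permutations = 0, seed = NULL) {
  if (inherits(pops, "coi_popmap")) {
    pops <- unname(pops$assignments[rownames(d2)])
  }
  if (!is.null(seed)) set.seed(seed)
  pop_levels <- unique(pops)
  P <- length(pop_levels)
  phi <- matrix(0, P, P, dimnames = list(pop_levels, pop_levels))
  pv <- matrix(NA_real_, P, P, dimnames = list(pop_levels, pop_levels))
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    keep <- pops %in% pop_levels[c(a, b)]
    sub <- d2[keep, keep, drop = FALSE]
    res <- amova(sub, pops[keep], permutations = permutations)
    phi[a, b] <- phi[b, a] <- res$phi[["phi_ST"]]
    if (permutations > 0) pv[a, b] <- pv[b, a] <- res$p_values[["phi_ST"]]
  }
  list(phi_st = phi, p_values = pv)
}

# all partitions of `items` into exactly K non-empty unlabeled groups
partitions_into_k <- function(items, K) {
  n <- length(items)
  if (K == 1L) return(list(stats::setNames(rep(1L, n), items)))
  if (K == n) return(list(stats::setNames(seq_len(n), items)))
  if (K > n) stop("K exceeds number of items")
  # restricted growth strings: a[i] <= 1 + max(a[1..i-1]), max+1 == K
  out <- list()
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      if (mx == K) out[[length(out) + 1L]] <<- stats::setNames(a, items)
      return(invisible())
    }
    if (mx + (n - i + 1L) < K) return(invisible()) # cannot reach K groups
    for (v in seq_len(min(mx + 1L, K))) {
      a[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  rec(1L, 0L)
  out
}

#' SAMOVA-style search for the best K-group partition of populations
#'
#' Finds the partition of populations into `K` groups maximizing the
#' among-group fixation index `Phi_CT`. For small problems (Bell-style
#' partition count below `exhaustive_limit`) every partition into exactly
#' `K` non-empty groups is enumerated; otherwise a simulated-annealing
#' search (single-population moves, geometric cooling, multiple random
#' starts) is used. Geographic contiguity is not enforced.
#'
#' @inheritParams amova
#' @param K Number of groups, `2 <= K < number of populations`.
#' @param n_starts Annealing restarts (when not exhaustive).
#' @param cooling Geometric cooling factor.
#' @param steps Annealing steps per start.
#' @param exhaustive_limit Enumerate exhaustively below this many
#'   candidate partitions.
#' @param permutations Permutations for the final AMOVA of the best
#'   partition.
#' @return List with `groups` (population -> group id), `phi_CT`, `amova`
#'   (full two-level `coi_amova` of the best partition) and `method`.
#' @export
samova <- function(d2, pops, K, n_starts = 100, cooling = 0.95,
                   steps = 200, exhaustive_limit = 1e5,
                   permutations = 0, seed = NULL) {
  if (inherits(pops, "coi_popmap")) {
    pops <- unname(pops$assignments[rownames(d2)])
  }
  pop_levels <- unique(pops)
  P <- length(pop_levels)
  if (K < 2L || K >= P) stop("K must satisfy 2 <= K < number of populations")
  if (!is.null(seed)) set.seed(seed)
  phi_ct_of <- function(assign) {
    amova_components(d2, pops, stats::setNames(assign, pop_levels))$phi[[
      "phi_CT"]]
  }
  n_parts <- stirling2(P, K)
  if (n_parts <= exhaustive_limit) {
    parts <- partitions_into_k(pop_levels, K)
    vals <- vapply(parts, function(p) phi_ct_of(unname(p)), numeric(1L))
    best <- parts[[which.max(vals)]]
    method <- "exhaustive"
  } else {
    best_val <- -Inf
    best <- NULL
    for (s in seq_len(n_starts)) {
      assign <- sample(c(seq_len(K), sample.int(K, P - K, replace = TRUE)))
      cur_val <- phi_ct_of(assign)
      temp <- 1
      for (st in seq_len(steps)) {
        cand <- assign
        i <- sample.int(P, 1L)
        dest <- setdiff(seq_len(K), assign[i])
        cand[i] <- dest[sample.int(length(dest), 1L)]
        if (length(unique(cand)) < K) next
        v <- phi_ct_of(cand)
        if (v > cur_val || stats::runif(1L) < exp((v - cur_val) / temp)) {
          assign <- cand
          cur_val <- v
        }
        temp <- temp * cooling
      }
      if (cur_val > best_val) {
        best_val <- cur_val
        best <- stats::setNames(assign, pop_levels)
      }
    }
    method <- "annealing"
  }
  grp <- stats::setNames(paste0("G", best), names(best))
  fit <- amova(d2, pops, groups = grp, permutations = permutations)
  list(groups = grp, phi_CT = fit$phi[["phi_CT"]], amova = fit,
       method = method)
}

# Stirling number of the second kind (count of partitions into K groups)
stirling2 <- function(n, k) {
  s <- matrix(0, n + 1L, k + 1L)
  s[1L, 1L] <- 1
  for (i in seq_len(n)) for (j in seq_len(min(i, k))) {
    s[i + 1L, j + 1L] <- j * s[i, j + 1L] + s[i, j]
  }
  s[n + 1L, k + 1L]
}
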
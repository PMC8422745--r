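# Molecular diversity indices: haplotype diversity (Hd), mean pairwise
# differences (K) and per-site nucleotide diversity (pi), with the Nei
# (1987) sampling variances that the standard single-locus tools report.
#
# pi is the raw proportion of differing included sites (p-distance); the
# substitution-model corrected distances live in the distance/tree module.

#' Haplotype (gene) diversity with sampling standard deviation
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` with the Nei (1987, eq. 8.12)
#' large-sample variance.
#'
#' @param counts Non-negative integer vector of haplotype counts for one
#'   population (zeros allowed).
#' @return List with `Hd`, `SD` and `n`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2 sequences")
  p <- counts / n
  sp2 <- sum(p^2)
  hd <- n / (n - 1) * (1 - sp2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  list(Hd = hd, SD = sqrt(max(v, 0)), n = n)
}

# pairwise difference counts on included sites, as a dense n x n matrix;
# duplicate rows are collapsed first so the quadratic work runs over
# distinct sequences only
pairdiff_matrix <- function(seqmat) {
  n <- nrow(seqmat)
  d <- matrix(0, n, n, dimnames = list(rownames(seqmat), rownames(seqmat)))
  if (n < 2) return(d)
  key <- apply(seqmat, 1L, paste, collapse = "")
  uniq <- unique(key)
  idx <- match(key, uniq)
  u <- length(uniq)
  if (u > 1L) {
    umat <- seqmat[match(uniq, key), , drop = FALSE]
    du <- matrix(0, u, u)
    for (i in seq_len(u - 1L)) {
      for (j in (i + 1L):u) {
        du[i, j] <- du[j, i] <- sum(umat[i, ] != umat[j, ])
      }
    }
    d[] <- du[idx, idx]
  }
  d
}

#' Nucleotide diversity and mean pairwise differences
#'
#' `K` is the mean number of differing included sites over all
#' `n(n-1)/2` sequence pairs; `pi = K / included_sites`. The standard
#' deviation of `pi` is the Nei (1987, eq. 10.7) total variance
#' (no-recombination form).
#'
#' @param aln A `coi_alignment` (all sequences of one population).
#' @return List with `pi`, `SD`, `K`, `n` and `sites` (included sites).
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  n <- length(aln$ids)
  if (n < 2) stop("nucleotide diversity needs n >= 2 sequences")
  inc <- included_sites(aln)
  L <- length(inc)
  if (L == 0L) stop("no included sites after complete deletion")
  sub <- aln$seqs[, inc, drop = FALSE]
  d <- pairdiff_matrix(sub)
  K <- sum(d[upper.tri(d)]) / choose(n, 2)
  pi <- K / L
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, SD = sqrt(max(v, 0)), K = K, n = n, sites = L)
}

# restrict an alignment to a subset of samples (keeps full columns so that
# per-population complete deletion is re-applied consistently with the
# pooled analysis: included sites are determined on the full alignment by
# the caller when comparability matters)
subset_alignment <- function(aln, keep) {
  new_alignment(aln$ids[keep],
                apply(aln$seqs[keep, , drop = FALSE], 1L, paste,
                      collapse = ""))
}

#' Per-population diversity table
#'
#' One row per population plus a pooled row (all sequences together),
#' mirroring the usual "mean/total" row of diversity tables.
#'
#' @param aln A `coi_alignment`.
#' @param pm A `coi_popmap`.
#' @param pooled_label Label for the pooled row (default `"Pooled"`).
#' @return data.frame with columns Population, n, h, h_prime, S, K, Hd,
#'   Hd_SD, pi, pi_SD.
#' @export
diversity_table <- function(aln, pm, pooled_label = "Pooled") {
  pops <- pop_labels(aln, pm)
  ht <- collapse_haplotypes(aln, pm)
  su <- shared_and_unique(ht)$per_population
  rows <- lapply(unique(pops), function(p) {
    sub <- subset_alignment(aln, pops == p)
    ss <- site_summary(sub)
    nd <- nucleotide_diversity(sub)
    hd <- haplotype_diversity(ht$counts[, p])
    data.frame(Population = p, n = nd$n,
               h = su$h[su$population == p],
               h_prime = su$h_prime[su$population == p],
               S = ss$S, K = nd$K, Hd = hd$Hd, Hd_SD = hd$SD,
               pi = nd$pi, pi_SD = nd$SD, stringsAsFactors = FALSE)
  })
  ss <- site_summary(aln)
  nd <- nucleotide_diversity(aln)
  hd <- haplotype_diversity(rowSums(ht$counts))
  pooled <- data.frame(Population = pooled_label, n = nd$n,
                       h = length(ht$haplotype_id),
                       h_prime = NA_integer_,
                       S = ss$S, K = nd$K, Hd = hd$Hd, Hd_SD = hd$SD,
                       pi = nd$pi, pi_SD = nd$SD, stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), pooled)
}
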
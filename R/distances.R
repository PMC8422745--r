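# Kimura 2-parameter distances, between-population average distances, and
# UPGMA / neighbor-joining dendrograms.
#
# K2P uses pairwise deletion of missing data within each sequence pair
# (the convention of the distance/tree tool chain), unlike the complete
# deletion used for S / pi / K upstream; both conventions are documented.

#' Kimura 2-parameter distance between two sequences
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion over sites valid in both sequences
#' (pairwise deletion).
#'
#' @param seq_a,seq_b Nucleotide strings (or character vectors) of equal
#'   length.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else
    toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else
    toupper(seq_b)
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites after pairwise deletion")
  a <- a[ok]
  b <- b[ok]
  m <- length(a)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / m
  Q <- sum(diff & !transition) / m
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("K2P distance undefined (saturation): P=", P, " Q=", Q)
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

# sample-level K2P matrix via ape (pairwise deletion), labels preserved
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  db <- ape::as.DNAbin(tolower(aln$seqs))
  as.matrix(ape::dist.dna(db, model = "K80", pairwise.deletion = TRUE))
}

#' Average between-population K2P distance matrix
#'
#' Entry (x, y) is the mean K2P distance over all inter-population
#' sequence pairs; the diagonal carries the mean within-population
#' distance.
#'
#' @param aln A `coi_alignment`.
#' @param pm A `coi_popmap`.
#' @param net If `TRUE`, report the net distance
#'   `d_A = d_xy - (d_xx + d_yy)/2` instead of the plain average.
#' @return List with `between` (symmetric matrix, population labels;
#'   diagonal zero), `within` (named vector of mean within-population
#'   distances) and `kind`.
#' @export
between_population_distance <- function(aln, pm, net = FALSE) {
  pops <- pop_labels(aln, pm)
  pop_levels <- unique(pops)
  if (length(pop_levels) < 2L) stop("need at least 2 populations")
  dm <- k2p_matrix(aln)
  P <- length(pop_levels)
  within <- stats::setNames(numeric(P), pop_levels)
  for (p in pop_levels) {
    ix <- which(pops == p)
    if (length(ix) < 1L) stop("empty population: ", p)
    within[p] <- if (length(ix) < 2L) 0 else
      mean(dm[ix, ix][upper.tri(dm[ix, ix])])
  }
  out <- matrix(0, P, P, dimnames = list(pop_levels, pop_levels))
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    ia <- which(pops == pop_levels[a])
    ib <- which(pops == pop_levels[b])
    d <- mean(dm[ia, ib])
    if (net) d <- d - (within[a] + within[b]) / 2
    out[a, b] <- out[b, a] <- d
  }
  list(between = out, within = within,
       kind = if (net) "net" else "average")
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square")
  }
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  if (is.null(rownames(dm))) stop("distance matrix needs labels")
  invisible(dm)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Size-weighted average linkage; node heights are half the merge
#' distance, so the tree is ultrametric.
#'
#' @param dm Symmetric labeled distance matrix.
#' @return A rooted `phylo` object (method tag in `attr(,"method")`).
#' @export
upgma_tree <- function(dm) {
  check_distance_matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels")
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "method") <- "UPGMA"
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion with standard branch lengths. Negative branch
#' lengths are set to zero with the difference transferred to the adjacent
#' branch.
#'
#' @param dm Symmetric labeled distance matrix.
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  check_distance_matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 labels")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    child <- tr$edge[e, 2L]
    # transfer the deficit to the sibling/adjacent branches of the node
    adj <- which(tr$edge[, 1L] == tr$edge[e, 1L] & seq_len(nrow(tr$edge)) !=
                   e)
    tr$edge.length[adj] <- tr$edge.length[adj] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  attr(tr, "method") <- "NJ"
  tr
}

#' Is a label the first to split from all others in a dendrogram?
#'
#' Reads a tree the way dendrogram figures are read: the tree is rooted
#' (unrooted trees are midpoint-rooted first) and the label is "separate"
#' when one child clade of the root is exactly that single label, i.e. the
#' label is sister to everything else.
#'
#' @param tree A `phylo` object.
#' @param label A tip label.
#' @return `TRUE`/`FALSE`.
#' @export
isolated_in_tree <- function(tree, label) {
  stopifnot(inherits(tree, "phylo"))
  if (!label %in% tree$tip.label) stop("label not in tree: ", label)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  clades <- lapply(kids, function(k) {
    if (k <= n) tree$tip.label[k] else ape::extract.clade(tree, k)$tip.label
  })
  any(vapply(clades, function(cl) identical(cl, label), logical(1L)))
}
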
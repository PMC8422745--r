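# Statistical-parsimony (TCS-style) haplotype network.
#
# The network is the minimum-spanning-network variant of statistical
# parsimony (epsilon = 0): haplotype pairs are joined in ascending order
# of mutational distance, all co-minimal alternative connections are
# retained (cycles allowed), and pairs farther apart than the parsimony
# connection limit are never joined directly. Unsampled intermediate
# states are inserted as median nodes so that every drawn edge is exactly
# one mutational step. Gaps are excluded from step counting (consistent
# with complete deletion upstream).

#' Parsimony connection limit
#'
#' Largest number of mutational steps `j` such that the probability that
#' `j` mutations on a sequence of `n_sites` sites all strike distinct
#' sites (i.e. produce `j` visible differences with no superimposed
#' change, the parsimony condition) is at least `confidence`. Computed by
#' the recursion `P(1) = 1`, `P(j) = P(j-1) * (1 - (j-1)/n_sites)`.
#'
#' @param n_sites Number of sites available for mutation (>= 1).
#' @param confidence Required parsimony probability (default 0.95;
#'   `confidence = 0` imposes no restriction).
#' @return Maximum connectable steps (integer).
#' @export
parsimony_connection_limit <- function(n_sites, confidence = 0.95) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (confidence <= 0) return(as.integer(n_sites))
  p <- 1
  j <- 1L
  while (j < n_sites) {
    p_next <- p * (1 - j / n_sites)
    if (p_next < confidence) break
    p <- p_next
    j <- j + 1L
  }
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' @param ht A `coi_haplotable` (see [collapse_haplotypes()]).
#' @param limit Maximum mutational steps for a direct connection (default:
#'   [parsimony_connection_limit()] on the included sites at 95%).
#' @return A `coi_haplonet`: list with `nodes` (data.frame: id, type
#'   sampled/median, frequency, one count column per population), `edges`
#'   (data.frame: from, to; each edge = 1 step), `hap_distances` (pairwise
#'   step counts between sampled haplotypes) and `limit`.
#' @export
build_tcs_network <- function(ht, limit = NULL) {
  stopifnot(inherits(ht, "coi_haplotable"))
  seqmat <- do.call(rbind, strsplit(ht$sequence, "", fixed = TRUE))
  rownames(seqmat) <- ht$haplotype_id
  H <- nrow(seqmat)
  if (is.null(limit)) {
    limit <- parsimony_connection_limit(ncol(seqmat))
  }
  d <- pairdiff_matrix(seqmat)
  nodes <- data.frame(id = ht$haplotype_id, type = "sampled",
                      frequency = rowSums(ht$counts),
                      stringsAsFactors = FALSE)
  for (p in colnames(ht$counts)) nodes[[paste0("count_", p)]] <-
    ht$counts[, p]
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  median_count <- 0L
  add_path <- function(a, b) {
    # insert d-1 median nodes between haplotypes a and b; differing sites
    # are switched in ascending column order (deterministic tie-break)
    sa <- seqmat[a, ]
    sb <- seqmat[b, ]
    sites <- which(sa != sb)
    cur_id <- a
    cur_seq <- sa
    for (s in seq_along(sites)) {
      if (s == length(sites)) {
        nxt_id <- b
      } else {
        median_count <<- median_count + 1L
        nxt_id <- paste0("median_", median_count)
        row <- nodes[1L, ]
        row$id <- nxt_id
        row$type <- "median"
        row$frequency <- 0
        row[grep("^count_", names(row))] <- 0
        nodes <<- rbind(nodes, row)
      }
      edges <<- rbind(edges, data.frame(from = cur_id, to = nxt_id,
                                        stringsAsFactors = FALSE))
      cur_seq[sites[s]] <- sb[sites[s]]
      cur_id <- nxt_id
    }
  }
  if (H > 1L) {
    comp <- seq_len(H) # union-find over sampled haplotypes
    find <- function(x) {
      while (comp[x] != x) x <- comp[x]
      x
    }
    dists <- sort(unique(d[upper.tri(d)]))
    dists <- dists[dists > 0 & dists <= limit]
    for (delta in dists) {
      # co-minimal rule: connectivity is frozen at the start of the class
      comp_before <- vapply(seq_len(H), find, integer(1L))
      pairs <- which(d == delta & upper.tri(d), arr.ind = TRUE)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]
        j <- pairs[r, 2L]
        if (comp_before[i] != comp_before[j]) {
          add_path(ht$haplotype_id[i], ht$haplotype_id[j])
          comp[find(i)] <- find(j)
        }
      }
    }
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, hap_distances = d,
                 limit = limit, total_n = ht$total_n),
            class = "coi_haplonet")
}

#' @export
print.coi_haplonet <- function(x, ...) {
  cat("<coi_haplonet> ", sum(x$nodes$type == "sampled"), " haplotypes + ",
      sum(x$nodes$type == "median"), " median nodes, ", nrow(x$edges),
      " edges (limit ", x$limit, " steps)\n", sep = "")
  invisible(x)
}

# igraph view of the network (used for GraphML export and centrality)
network_igraph <- function(net) {
  stopifnot(inherits(net, "coi_haplonet"))
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = net$nodes)
  igraph::E(g)$steps <- rep(1L, igraph::ecount(g))
  g
}

#' Central (candidate ancestral) haplotype of a network
#'
#' The sampled node with the highest frequency; ties broken by minimum
#' graph eccentricity, then lexicographic id. In star-like intraspecific
#' genealogies this is the natural candidate for the ancestral haplotype.
#'
#' @param net A `coi_haplonet`.
#' @return A haplotype id.
#' @export
central_haplotype <- function(net) {
  stopifnot(inherits(net, "coi_haplonet"))
  nodes <- net$nodes[net$nodes$type == "sampled", ]
  if (nrow(nodes) == 0L) stop("empty network")
  best <- nodes[nodes$frequency == max(nodes$frequency), ]
  if (nrow(best) > 1L) {
    g <- network_igraph(net)
    ecc <- igraph::eccentricity(g, vids = best$id)
    best <- best[ecc == min(ecc), , drop = FALSE]
    best <- best[order(best$id), , drop = FALSE]
  }
  best$id[1L]
}
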
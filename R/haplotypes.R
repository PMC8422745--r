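# Haplotype collapsing and polymorphic-site characterization.
#
# Missing data ('-' or 'N') are handled by complete deletion: any column
# containing a missing state in any sequence is excluded before haplotype
# collapsing and before S / K / pi computation. The number of excluded
# columns is always reported.

MISSING_STATES <- c("N", "-")

#' Indices of alignment columns free of missing data
#'
#' @param aln A `coi_alignment`.
#' @return Integer vector of column indices with no `-` or `N` in any
#'   sequence ("complete deletion" columns).
#' @export
included_sites <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  which(colSums(matrix(aln$seqs %in% MISSING_STATES,
                       nrow = nrow(aln$seqs))) == 0L)
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical on included sites (columns free of missing data)
#' share a haplotype. Haplotype ids are assigned `Hap_1, Hap_2, ...` in
#' descending order of total count, ties broken by first occurrence in the
#' alignment, so the modal haplotype is always `Hap_1`.
#'
#' @param aln A `coi_alignment`.
#' @param pm A `coi_popmap` covering every sample. If `NULL`, all samples
#'   are treated as one population `"all"`.
#' @return A `coi_haplotable`: list with `haplotype_id`, `sequence`
#'   (included-sites string per haplotype), `full_sequence` (a
#'   representative full-length sequence), `counts` (haplotype x population
#'   integer matrix), `total_n`, `included` (column indices used),
#'   `excluded_sites`, `assignment` (named haplotype id per sample).
#' @export
collapse_haplotypes <- function(aln, pm = NULL) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (is.null(pm)) {
    pm <- new_population_map(aln$ids, rep("all", length(aln$ids)))
  }
  pops <- pop_labels(aln, pm)
  inc <- included_sites(aln)
  key <- unname(apply(aln$seqs[, inc, drop = FALSE], 1L, paste,
                      collapse = ""))
  first <- !duplicated(key)
  uniq <- key[first]
  total <- as.vector(table(factor(key, levels = uniq)))
  ord <- order(-total, seq_along(uniq))
  uniq <- uniq[ord]
  ids <- paste0("Hap_", seq_along(uniq))
  hap_of_sample <- ids[match(key, uniq)]
  pop_levels <- unique(pops)
  counts <- table(factor(hap_of_sample, levels = ids),
                  factor(pops, levels = pop_levels))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, pop_levels))
  rep_full <- aln$seqs[match(uniq, key), , drop = FALSE]
  structure(list(
    haplotype_id = ids,
    sequence = uniq,
    full_sequence = unname(apply(rep_full, 1L, paste, collapse = "")),
    counts = counts,
    total_n = length(key),
    included = inc,
    excluded_sites = aln$length - length(inc),
    assignment = stats::setNames(hap_of_sample, aln$ids)
  ), class = "coi_haplotable")
}

#' @export
print.coi_haplotable <- function(x, ...) {
  cat("<coi_haplotable> ", length(x$haplotype_id), " haplotypes, ",
      x$total_n, " sequences, ", ncol(x$counts), " population(s); ",
      x$excluded_sites, " excluded site(s)\n", sep = "")
  invisible(x)
}

#' Summarize polymorphic sites of an alignment
#'
#' Computed on included (complete-deletion) columns. A site is segregating
#' if at least two distinct bases occur; parsimony-informative if at least
#' two bases each occur at least twice; otherwise it is a singleton site.
#'
#' @param aln A `coi_alignment`.
#' @return List with `S`, `parsimony_informative`, `singleton_sites`,
#'   `excluded_sites`, `included_sites`.
#' @export
site_summary <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  inc <- included_sites(aln)
  sub <- aln$seqs[, inc, drop = FALSE]
  pi_count <- 0L
  s_count <- 0L
  for (j in seq_len(ncol(sub))) {
    tab <- tabulate(factor(sub[, j], levels = c("A", "C", "G", "T")), 4L)
    if (sum(tab > 0L) >= 2L) {
      s_count <- s_count + 1L
      if (sum(tab >= 2L) >= 2L) pi_count <- pi_count + 1L
    }
  }
  list(S = s_count,
       parsimony_informative = pi_count,
       singleton_sites = s_count - pi_count,
       excluded_sites = aln$length - length(inc),
       included_sites = length(inc))
}

#' Per-population haplotype richness and cross-population sharing
#'
#' @param ht A `coi_haplotable`.
#' @return List with `per_population` (data.frame: population, n, h = number
#'   of haplotypes present, h_prime = haplotypes private to that
#'   population), `shared_ids` (haplotypes present in two or more
#'   populations) and `n_shared`.
#' @export
shared_and_unique <- function(ht) {
  stopifnot(inherits(ht, "coi_haplotable"))
  present <- ht$counts > 0L
  npop_of_hap <- rowSums(present)
  per_pop <- data.frame(
    population = colnames(ht$counts),
    n = colSums(ht$counts),
    h = colSums(present),
    h_prime = colSums(present & npop_of_hap == 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  shared <- ht$haplotype_id[npop_of_hap >= 2L]
  list(per_population = per_pop, shared_ids = shared,
       n_shared = length(shared))
}

#' Expand a haplotype table back into an alignment + population map
#'
#' Inverse of [collapse_haplotypes()] up to sample naming: each haplotype is
#' replicated according to its per-population counts. This is the input mode
#' for studies distributed as haplotype sequences plus a count table.
#'
#' @param ht A `coi_haplotable`, or a data.frame in the layout written by
#'   [write_haplotype_table()].
#' @return List with `alignment` (a `coi_alignment`) and `popmap`
#'   (a `coi_popmap`).
#' @export
expand_haplotype_table <- function(ht) {
  if (is.data.frame(ht)) ht <- haplotable_from_df(ht)
  stopifnot(inherits(ht, "coi_haplotable"))
  ids <- character(0)
  seqs <- character(0)
  pops <- character(0)
  for (p in colnames(ht$counts)) {
    for (i in seq_along(ht$haplotype_id)) {
      k <- ht$counts[i, p]
      if (k > 0L) {
        new_ids <- paste0(p, "_", ht$haplotype_id[i], "_", seq_len(k))
        ids <- c(ids, new_ids)
        seqs <- c(seqs, rep(ht$full_sequence[i], k))
        pops <- c(pops, rep(p, k))
      }
    }
  }
  aln <- new_alignment(ids, seqs)
  list(alignment = aln, popmap = new_population_map(ids, pops))
}

#' Write a haplotype table as CSV
#'
#' Layout: one row per haplotype with columns `haplotype_id`, one count
#' column per population, and `sequence`.
#'
#' @param ht A `coi_haplotable`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_haplotype_table <- function(ht, path) {
  stopifnot(inherits(ht, "coi_haplotable"))
  df <- data.frame(haplotype_id = ht$haplotype_id,
                   ht$counts, check.names = FALSE,
                   sequence = ht$full_sequence,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a haplotype table written by [write_haplotype_table()]
#'
#' @param path CSV path.
#' @return A `coi_haplotable`.
#' @export
read_haplotype_table <- function(path) {
  if (!file.exists(path)) stop("haplotype table not found: ", path)
  haplotable_from_df(utils::read.csv(path, check.names = FALSE,
                                     stringsAsFactors = FALSE))
}

haplotable_from_df <- function(df) {
  need <- c("haplotype_id", "sequence")
  if (!all(need %in% names(df))) {
    stop("haplotype table needs columns 'haplotype_id' and 'sequence'")
  }
  popcols <- setdiff(names(df), need)
  counts <- as.matrix(df[, popcols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$haplotype_id
  seqs <- toupper(df$sequence)
  structure(list(
    haplotype_id = df$haplotype_id,
    sequence = seqs,
    full_sequence = seqs,
    counts = counts,
    total_n = sum(counts),
    included = seq_len(nchar(seqs[1L])),
    excluded_sites = 0L,
    assignment = NULL
  ), class = "coi_haplotable")
}
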
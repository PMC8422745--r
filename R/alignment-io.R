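#' Read a multiple-sequence alignment from FASTA
#'
#' Reads an aligned nucleotide FASTA file into a `coi_alignment` object.
#' Sequences are uppercased on ingest; the alphabet is restricted to
#' `A,C,G,T,N,-` and all sequences must have identical length (it is an
#' alignment, not a sequence set). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A `coi_alignment`: a list with `ids` (character), `seqs`
#'   (character matrix, samples x sites) and `length` (number of sites).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  new_alignment(names(ss), toupper(as.character(ss)))
}

#' Construct an alignment from id and sequence vectors
#'
#' @param ids Character vector of unique sample identifiers.
#' @param seqs Character vector of equal-length nucleotide strings
#'   (alphabet `A,C,G,T,N,-`; lowercase accepted).
#' @return A `coi_alignment` object.
#' @export
new_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(ids) == 0L) stop("empty alignment")
  if (anyDuplicated(ids)) {
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]][1L]
    stop("unequal sequence lengths (not an alignment): record '", bad,
         "' has ", w[ids == bad][1L], " sites, expected ", w[1L])
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  ok <- mat %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(mat)), arr.ind = TRUE)[1L, ]
    stop("illegal character '", mat[bad[1L], bad[2L]], "' in record '",
         ids[bad[1L]], "' at column ", bad[2L])
  }
  structure(list(ids = ids, seqs = mat, length = ncol(mat)),
            class = "coi_alignment")
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat("<coi_alignment> ", length(x$ids), " sequences x ", x$length,
      " sites\n", sep = "")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln A `coi_alignment`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "coi_alignment"))
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Accepts a CSV with header `sample_id,population` or a two-column
#' whitespace-delimited file without header. Optional columns `latitude`
#' and `longitude` (per population) are carried along when present.
#'
#' @param path Path to the map file.
#' @return A `coi_popmap`: list with `assignments` (named character vector,
#'   sample_id -> population) and optional `coordinates` (data.frame with
#'   population, latitude, longitude).
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "population") %in% names(df))) {
      stop("population map must have columns 'sample_id' and 'population', ",
           "found: ", paste(names(df), collapse = ", "))
    }
  } else {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("population map needs two columns in ", path)
    names(df)[1:2] <- c("sample_id", "population")
  }
  new_population_map(df$sample_id, df$population,
                     coordinates = if (all(c("latitude", "longitude") %in%
                                           names(df))) {
                       unique(df[, c("population", "latitude", "longitude")])
                     })
}

#' Construct a population map
#'
#' @param sample_ids Character vector of sample ids (unique).
#' @param populations Character vector of population labels, parallel to
#'   `sample_ids`.
#' @param coordinates Optional data.frame with columns population, latitude,
#'   longitude.
#' @return A `coi_popmap` object.
#' @export
new_population_map <- function(sample_ids, populations, coordinates = NULL) {
  sample_ids <- as.character(sample_ids)
  populations <- as.character(populations)
  if (length(sample_ids) != length(populations)) {
    stop("sample_ids and populations differ in length")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample_id in population map: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!nzchar(populations)) || anyNA(populations)) {
    stop("empty population label in map")
  }
  assignments <- stats::setNames(populations, sample_ids)
  structure(list(assignments = assignments, coordinates = coordinates),
            class = "coi_popmap")
}

#' @export
print.coi_popmap <- function(x, ...) {
  tab <- table(x$assignments)
  cat("<coi_popmap> ", length(x$assignments), " samples, ",
      length(tab), " populations\n", sep = "")
  print(tab)
  invisible(x)
}

# population labels of an alignment's samples, in alignment order;
# errors if any sample is unmapped
pop_labels <- function(aln, pm) {
  lab <- pm$assignments[aln$ids]
  if (anyNA(lab)) {
    stop("samples missing from population map: ",
         paste(aln$ids[is.na(lab)], collapse = ", "))
  }
  unname(lab)
}

#' Write a results table as delimited text
#'
#' Numeric columns are formatted to a fixed number of decimals (default 4,
#' the precision used for diversity and Phi statistics; use 3 for D / Fs
#' style columns via `digits`).
#'
#' @param rows A data.frame.
#' @param path Output CSV path.
#' @param digits Decimals for numeric columns (single value or named vector
#'   per column).
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(rows, path, digits = 4) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      d <- if (length(digits) > 1L && nm %in% names(digits)) {
        digits[[nm]]
      } else if (length(digits) == 1L) digits else 4
      out[[nm]] <- formatC(out[[nm]], digits = d, format = "f")
    }
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write table to ", path)
  invisible(path)
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` object (as produced by [upgma_tree()] or
#'   [nj_tree()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ok <- try(ape::write.tree(tree, file = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write newick to ", path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  ape::read.tree(path)
}

#' Write a haplotype network to GraphML (or CSV edge list)
#'
#' Node attributes carry total frequency and per-population counts
#' (`count_<population>`); every edge is a single mutational step.
#'
#' @param net A `coi_haplonet` (see [build_tcs_network()]).
#' @param path Output path; format chosen by extension (`.graphml` or
#'   `.csv` edge list).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  g <- network_igraph(net)
  if (grepl("\\.csv$", path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.csv(el, path, row.names = FALSE)
  } else {
    ok <- try(igraph::write_graph(g, path, format = "graphml"),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write network to ", path)
  }
  invisible(path)
}

#' Read a population-level distance matrix from CSV
#'
#' Expects a square matrix with row and column labels (first column = row
#' labels), such as a published between-population distance table. Only one
#' triangle need be filled; the matrix is symmetrized and the diagonal
#' zeroed.
#'
#' @param path CSV path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stop("distance matrix not found: ", path)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance matrix is not square in ", path)
  m[is.na(m)] <- 0
  m <- m + t(m)
  # if both triangles were present they are now doubled; detect and halve
  if (max(abs(m - t(m))) > 0) stop("inconsistent distance matrix in ", path)
  ut <- upper.tri(df)
  if (any(!is.na(as.matrix(df)[ut]) & as.matrix(df)[ut] != 0) &&
      any(!is.na(as.matrix(df)[lower.tri(df)]) &
          as.matrix(df)[lower.tri(df)] != 0)) {
    m <- m / 2
  }
  diag(m) <- 0
  m
}
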
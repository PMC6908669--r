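## Sequence conservation and relatedness: per-column Shannon entropy, pairwise
## Hamming distance matrices (global and region-restricted through a
## structure -> alignment mapping), and UPGMA cladograms with Newick output.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")

#' Construct an MSA
#'
#' @param ids unique sequence identifiers
#' @param seqs character vector of equal-length aligned sequences over the 20
#'   amino acids plus gap '-' and unknown 'X'
#' @param reference_id optional id of the row used for residue mapping
#' @export
msa <- function(ids, seqs, reference_id = NULL) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  bad <- setdiff(unique(as.vector(mat)), AA_ALPHABET)
  if (length(bad)) stop("symbols outside the amino-acid alphabet: ",
                        paste(bad, collapse = " "))
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop("reference_id not among sequence ids")
  rownames(mat) <- ids
  structure(list(ids = ids, matrix = mat, reference_id = reference_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Read an aligned FASTA file as an MSA
#' @param path aligned FASTA
#' @param reference_id optional reference row id
#' @return an [msa()]
#' @export
read_msa_fasta <- function(path, reference_id = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  msa(ids, as.character(ss), reference_id = reference_id)
}

#' Write an MSA as aligned FASTA
#' @param x an [msa()]
#' @param path output path
#' @export
write_msa_fasta <- function(x, path) {
  seqs <- apply(x$matrix, 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- x$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Per-column Shannon entropy profile (bits)
#'
#' `s_c = -sum_a p_a log2 p_a` over the symbols present in column c. Under
#' gap policy "ignore" gaps are removed before computing frequencies (a column
#' of only gaps is NA, flagged in the `undefined` attribute); under "symbol"
#' the gap counts as a 21st symbol.
#'
#' @param x an [msa()]
#' @param gap_policy "ignore" (default) or "symbol"
#' @return numeric vector, one entry per column
#' @export
column_entropy_profile <- function(x, gap_policy = c("ignore", "symbol")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(nrow(x$matrix) >= 2)
  ent <- apply(x$matrix, 2, function(col) {
    if (gap_policy == "ignore") col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  out <- unname(ent)
  attr(out, "undefined") <- which(is.na(out))
  out
}

#' Pairwise Hamming distance matrix
#'
#' `d(a, b)` counts columns where the symbols differ. Under gap policy
#' "symbol" (default) the gap is an ordinary 21st symbol, which keeps the
#' matrix a metric; under "ignore", columns where either sequence has a gap
#' are skipped for that pair, and the normalized variant divides by the
#' compared-column count. Pairs with zero comparable columns are NA, flagged
#' in the `undefined` attribute.
#'
#' @param x an [msa()]
#' @param normalize divide by the number of compared columns
#' @param gap_policy "symbol" (default) or "ignore"
#' @return object of class `distance_matrix`: list(ids, matrix)
#' @export
hamming_distance_matrix <- function(x, normalize = FALSE,
                                    gap_policy = c("symbol", "ignore")) {
  gap_policy <- match.arg(gap_policy)
  m <- x$matrix
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  undef <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- m[i, ]; b <- m[j, ]
      if (gap_policy == "ignore") {
        keep <- a != "-" & b != "-"
        a <- a[keep]; b <- b[keep]
      }
      nc <- length(a)
      if (nc == 0) {
        D[i, j] <- D[j, i] <- NA_real_
        undef <- rbind(undef, c(i, j))
        next
      }
      d <- sum(a != b)
      D[i, j] <- D[j, i] <- if (normalize) d / nc else d
    }
  }
  out <- structure(list(ids = x$ids, matrix = D), class = "distance_matrix")
  attr(out, "undefined") <- undef
  out
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d x %d\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' UPGMA cladogram from a distance matrix
#'
#' Size-weighted average-linkage agglomeration; a node joining clusters at
#' distance d sits at height d/2, so on ultrametric input the tree's
#' cophenetic distances reproduce the matrix exactly. Ties are made
#' deterministic by lexicographic pre-ordering of ids.
#'
#' @param d a `distance_matrix`
#' @return an [ape::phylo] rooted tree with branch lengths; attribute
#'   `ultrametric` is TRUE (UPGMA trees are ultrametric by construction)
#' @export
upgma_tree <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (anyNA(d$matrix)) stop("distance matrix contains NA entries")
  if (length(d$ids) < 2) stop("need at least 2 ids")
  ord <- order(d$ids)
  M <- d$matrix[ord, ord]
  hc <- stats::hclust(stats::as.dist(M), method = "average")
  ## ape::as.phylo.hclust halves merge heights, so a node joining clusters at
  ## distance d sits at height d/2 and cophenetic distances reproduce d
  tr <- ape::as.phylo(hc)
  attr(tr, "ultrametric") <- TRUE
  tr
}

#' Write a cladogram as Newick
#' @param tree an `ape::phylo`
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Map structure residues to alignment columns via the reference row
#'
#' The k-th non-gap symbol of the reference row corresponds to ungapped
#' reference position k. `offset` places the structure's author numbering on
#' that scale: ungapped position = author resnum - offset + 1.
#'
#' @param x an [msa()] with `reference_id` set
#' @param structure_residues residue keys ("chain:resnum:icode")
#' @param offset author residue number of ungapped reference position 1
#' @return named integer vector: alignment column per residue key; unmappable
#'   residues are dropped with a warning
#' @export
map_structure_to_alignment <- function(x, structure_residues, offset = 1) {
  if (is.null(x$reference_id)) stop("msa has no reference_id")
  ref <- x$matrix[x$reference_id, ]
  cols_of_pos <- which(ref != "-")     # alignment column of ungapped pos k
  resnum <- as.integer(sub("^[^:]*:(-?[0-9]+):.*$", "\\1", structure_residues))
  pos <- resnum - offset + 1L
  ok <- !is.na(pos) & pos >= 1L & pos <= length(cols_of_pos)
  if (any(!ok))
    warning("unmappable residues skipped: ",
            paste(structure_residues[!ok], collapse = ", "))
  stats::setNames(cols_of_pos[pos[ok]], structure_residues[ok])
}

#' Region-restricted Hamming distance matrix
#'
#' Restricts the alignment to the columns mapped from a structural region
#' (e.g. a binding site) and computes the Hamming matrix on those columns
#' only.
#'
#' @param x an [msa()]
#' @param columns alignment columns (e.g. from
#'   [map_structure_to_alignment()])
#' @param normalize,gap_policy passed to [hamming_distance_matrix()]
#' @return a `distance_matrix`
#' @export
region_distance_submatrix <- function(x, columns, normalize = FALSE,
                                      gap_policy = c("symbol", "ignore")) {
  columns <- unique(as.integer(columns))
  stopifnot(length(columns) >= 1, all(columns >= 1),
            all(columns <= ncol(x$matrix)))
  sub <- x
  sub$matrix <- x$matrix[, columns, drop = FALSE]
  hamming_distance_matrix(sub, normalize = normalize, gap_policy = gap_policy)
}

#' Write a distance matrix as TSV and/or PHYLIP square format
#' @param d a `distance_matrix`
#' @param tsv_path,phylip_path output paths (NULL to skip)
#' @export
write_distance_matrix <- function(d, tsv_path = NULL, phylip_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(id = d$ids, d$matrix, check.names = FALSE)
    write_tsv_file(df, tsv_path)
  }
  if (!is.null(phylip_path)) write_phylip_square(d$matrix, d$ids, phylip_path)
  invisible(d)
}
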
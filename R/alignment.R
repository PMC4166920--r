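# Alignment container and preprocessing: FASTA/newick I/O, gap-threshold
# trimming, and per-gene concatenation with partition tracking.  An alignment
# is a character matrix (rows = taxa, single upper-case residues, '-' gap,
# 'X' unknown) with an optional "partition" attribute: a data.frame
# (gene, start, end) of 0-based half-open column intervals tiling the matrix.

#' Construct an amino-acid alignment
#'
#' @param x Character matrix of single characters; row names are taxon
#'   labels.  Lower-case input is upper-cased.
#' @param partition Optional data.frame with columns `gene`, `start`, `end`
#'   (0-based, half-open) tiling `[0, ncol)` without overlap.
#' @return Object of class `"aa_alignment"` (a character matrix).
#' @export
aa_alignment <- function(x, partition = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("alignment rows must carry unique taxon labels")
  if (ncol(x) > 0) {
    x[] <- toupper(x)
    bad <- setdiff(unique(as.vector(x)), c(aa_states(), "-", "X"))
    if (length(bad))
      stop("unsupported residue code(s): ", paste(bad, collapse = " "))
  }
  if (!is.null(partition)) {
    partition <- as.data.frame(partition)
    stopifnot(all(c("gene", "start", "end") %in% names(partition)))
    o <- order(partition$start)
    partition <- partition[o, , drop = FALSE]
    if (nrow(partition) &&
        (partition$start[1] != 0 ||
         partition$end[nrow(partition)] != ncol(x) ||
         any(partition$start[-1] != partition$end[-nrow(partition)])))
      stop("partition intervals must tile [0, ncol) without gaps or overlap")
    rownames(partition) <- NULL
  }
  structure(x, partition = partition, class = c("aa_alignment", class(x)))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d taxa x %d columns\n", nrow(x), ncol(x)))
  p <- attr(x, "partition")
  if (!is.null(p))
    cat(sprintf("  %d gene partition(s): %s\n", nrow(p),
                paste(utils::head(p$gene, 5), collapse = ", ")))
  invisible(x)
}

partition_of <- function(aln) attr(aln, "partition")

#' Read an aligned FASTA file
#'
#' All records must have equal length; duplicate labels are an error.
#'
#' @param path FASTA file path.
#' @return An [aa_alignment()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1)
    stop("ragged alignment: sequence lengths differ in ", path)
  labels <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(labels))
    stop("duplicate sequence labels in ", path)
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- labels
  aa_alignment(m)
}

#' Write an alignment as FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @inheritParams write_fasta
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln), ncol(aln)), con)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  invisible(path)
}

#' Read / write a newick tree
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' the result.
#'
#' @param path File path.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Trim alignment columns by gap content
#'
#' Mirrors trimAl-style gap-threshold trimming.  The published description
#' "gap threshold of 25%" admits two readings, both provided:
#' `"min_residue_fraction"` (the trimAl `-gt` convention: keep a column if
#' the fraction of non-gap residues is at least `gap_threshold`; the default)
#' and `"max_gap_fraction"` (keep a column if its gap fraction is at most
#' `gap_threshold`).  `'X'` counts as a residue, not a gap.  Column order is
#' preserved and the partition map is remapped to the surviving columns.
#'
#' @param aln An [aa_alignment()].
#' @param gap_threshold Fraction in `[0, 1]`, default 0.25.
#' @param gap_meaning `"min_residue_fraction"` or `"max_gap_fraction"`.
#' @return The trimmed [aa_alignment()].
#' @export
trim_alignment <- function(aln, gap_threshold = 0.25,
                           gap_meaning = c("min_residue_fraction",
                                           "max_gap_fraction")) {
  gap_meaning <- match.arg(gap_meaning)
  if (gap_threshold < 0 || gap_threshold > 1)
    stop("gap_threshold must be in [0, 1]")
  if (ncol(aln) == 0) return(aln)
  gap_frac <- colMeans(unclass(aln) == "-")
  keep <- switch(gap_meaning,
    min_residue_fraction = (1 - gap_frac) >= gap_threshold,
    max_gap_fraction = gap_frac <= gap_threshold)
  part <- partition_of(aln)
  out <- unclass(aln)[, keep, drop = FALSE]
  new_part <- NULL
  if (!is.null(part) && nrow(part)) {
    # surviving-column count per original interval
    cum <- cumsum(keep)
    n_kept <- vapply(seq_len(nrow(part)), function(i) {
      a <- part$start[i]; b <- part$end[i]
      (if (b > 0) cum[b] else 0L) - (if (a > 0) cum[a] else 0L)
    }, numeric(1))
    keep_genes <- n_kept > 0
    ends <- cumsum(n_kept[keep_genes])
    new_part <- data.frame(gene = part$gene[keep_genes],
                           start = c(0, utils::head(ends, -1)),
                           end = ends)
  }
  aa_alignment(out, partition = new_part)
}

#' Concatenate per-gene alignments into a superalignment
#'
#' Columns are appended in input order.  The taxon set is the union of input
#' taxa (order of first appearance); a taxon missing from a gene is padded
#' with gaps over that gene's columns.  The partition map records each gene's
#' 0-based half-open column interval.
#'
#' @param alignments List of [aa_alignment()] objects (length >= 1).
#' @param gene_ids Gene identifiers, one per alignment (default `g1, g2, ...`).
#' @return An [aa_alignment()] with a full partition map.
#' @export
concatenate_alignments <- function(alignments,
                                   gene_ids = paste0("g", seq_along(alignments))) {
  if (length(alignments) == 0) stop("need at least one alignment")
  if (length(gene_ids) != length(alignments))
    stop("gene_ids must match alignments in length")
  taxa <- unique(unlist(lapply(alignments, rownames)))
  lens <- vapply(alignments, ncol, integer(1))
  total <- sum(lens)
  out <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  for (a in alignments) {
    if (ncol(a) > 0) out[rownames(a), at + seq_len(ncol(a))] <- unclass(a)
    at <- at + ncol(a)
  }
  ends <- cumsum(lens)
  aa_alignment(out, partition = data.frame(
    gene = gene_ids, start = c(0, utils::head(ends, -1)), end = ends))
}

#' Write / read a partition map as TSV
#'
#' @param aln An [aa_alignment()] with a partition attribute.
#' @param path Output path.
#' @export
write_partition <- function(aln, path) {
  p <- partition_of(aln)
  if (is.null(p)) stop("alignment has no partition map")
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Convert to phangorn's phyDat ('-' and 'X' are treated as fully ambiguous).
as_phyDat <- function(aln) {
  phangorn::phyDat(unclass(aln), type = "AA")
}
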
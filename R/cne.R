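# Conserved-element scan on a pairwise alignment: slide a fixed window over
# alignment columns, qualify windows by percent identity, merge overlapping
# qualifying windows into maximal runs, drop runs overlapping an exon mask,
# and report reference (gap-stripped, 0-based half-open) coordinates.

#' Scan a pairwise alignment for conserved elements
#'
#' A window of `window` alignment columns qualifies when the fraction of
#' matching columns is at least `min_identity` (inclusive threshold).  By
#' default a column containing a gap in either row counts as a mismatch
#' (`count_gap_columns = TRUE`); alternatively gap columns can be excluded
#' from both numerator and denominator.  Overlapping qualifying windows are
#' merged into maximal runs; runs overlapping `exon_mask` intervals on the
#' reference are removed.
#'
#' @param reference,query Aligned sequences of equal length: character
#'   strings or character vectors of single characters, gaps as `"-"`.  A
#'   2-row [aa_alignment()] may be given as `reference` (first row =
#'   reference).
#' @param min_identity Identity threshold in `(0, 1]`, default 0.70.
#' @param window Window size in alignment columns, default 100.
#' @param exon_mask Optional data.frame with columns `start`, `end`
#'   (0-based half-open reference intervals), e.g. from [read_bed()].
#' @param count_gap_columns Count gap-containing columns as mismatches
#'   (default) instead of ignoring them.
#' @return data.frame of class `"cne_records"`: `ref_start`, `ref_end`,
#'   `length` (reference span), `aln_start`, `aln_end`, `aln_length`,
#'   `mean_identity`, sorted and disjoint on the reference.
#' @export
scan_cne <- function(reference, query = NULL, min_identity = 0.70,
                     window = 100L, exon_mask = NULL,
                     count_gap_columns = TRUE) {
  if (inherits(reference, "aa_alignment") && is.null(query)) {
    if (nrow(reference) != 2) stop("need exactly two aligned rows")
    query <- unclass(reference)[2, ]
    reference <- unclass(reference)[1, ]
  }
  to_chars <- function(x)
    if (length(x) == 1 && nchar(x[1]) > 1) strsplit(x, "")[[1]] else as.character(x)
  r <- toupper(to_chars(reference))
  q <- toupper(to_chars(query))
  if (length(r) != length(q)) stop("aligned rows differ in length")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  n <- length(r)
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      length = integer(0), aln_start = integer(0),
                      aln_end = integer(0), aln_length = integer(0),
                      mean_identity = numeric(0))
  class(empty) <- c("cne_records", "data.frame")
  if (n < window) return(empty)

  gap <- r == "-" | q == "-"
  match_col <- (r == q) & !gap
  if (count_gap_columns) {
    num <- as.numeric(match_col)
    den <- rep(1, n)
  } else {
    num <- as.numeric(match_col)
    den <- as.numeric(!gap)
  }
  csn <- c(0, cumsum(num))
  csd <- c(0, cumsum(den))
  starts <- seq_len(n - window + 1L)          # 1-based window starts
  wnum <- csn[starts + window] - csn[starts]
  wden <- csd[starts + window] - csd[starts]
  ok <- wden > 0 & (wnum / pmax(wden, 1)) >= min_identity

  if (!any(ok)) return(empty)
  # merge overlapping qualifying windows into maximal alignment-column runs
  idx <- which(ok)
  brk <- c(0, which(diff(idx) > window), length(idx))
  runs <- lapply(seq_len(length(brk) - 1L), function(i) {
    g <- idx[(brk[i] + 1L):brk[i + 1L]]
    c(min(g), max(g) + window - 1L)           # 1-based inclusive columns
  })
  ref_before <- c(0, cumsum(r != "-"))        # ref chars strictly before col
  recs <- do.call(rbind, lapply(runs, function(rg) {
    a <- rg[1]; b <- rg[2]
    mi <- (csn[b + 1] - csn[a]) / max(csd[b + 1] - csd[a], 1)
    data.frame(ref_start = ref_before[a], ref_end = ref_before[b + 1],
               length = ref_before[b + 1] - ref_before[a],
               aln_start = a - 1L, aln_end = b, aln_length = b - a + 1L,
               mean_identity = mi)
  }))
  if (!is.null(exon_mask) && nrow(recs)) {
    keep <- vapply(seq_len(nrow(recs)), function(i) {
      !any(recs$ref_start[i] < exon_mask$end &
             exon_mask$start < recs$ref_end[i])
    }, logical(1))
    recs <- recs[keep, , drop = FALSE]
  }
  rownames(recs) <- NULL
  class(recs) <- c("cne_records", "data.frame")
  recs
}

#' Summarise conserved-element records
#'
#' @param records A [scan_cne()] result.
#' @return List: `count`, `total_length`, `mean_size` (0 with `empty = TRUE`
#'   when there are no records).
#' @export
cne_summary <- function(records) {
  if (nrow(records) == 0)
    return(list(count = 0L, total_length = 0L, mean_size = 0, empty = TRUE))
  list(count = nrow(records),
       total_length = sum(records$length),
       mean_size = mean(records$length),
       empty = FALSE)
}

#' Read a BED file of intervals
#'
#' First three columns: chrom, start, end (0-based half-open).
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(tab[, 1:3], c("chrom", "start", "end"))
}

#' Write conserved-element records as BED
#'
#' @param records A [scan_cne()] result.
#' @param path Output path.
#' @param chrom Chromosome/scaffold name for column 1.
#' @export
write_cne_bed <- function(records, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = records$ref_start,
                   end = records$ref_end,
                   name = sprintf("CNE%d", seq_len(nrow(records))),
                   score = round(1000 * records$mean_identity))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
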
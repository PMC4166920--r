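# Gene- and cluster-level adjudication: the orthology-informative filter
# (guard against hidden paralogy), per-gene verdicts combining the
# maximum-likelihood hypothesis with AU rejections, cluster-level
# interleaving / tetralogy calls, and the dN/dS ratio summary.

#' Orthology-informative filter
#'
#' A query gene is orthology-informative only when at least one duplicated
#' ("clupeocephalan-like") species with a complete gene complement retains
#' both the "a" and "b" copy of its family; otherwise a lost duplicate could
#' make the query group with the surviving paralog (hidden paralogy) and the
#' gene is dropped.
#'
#' @param query_genes data.frame with columns `gene_id` and `family`.
#' @param retention data.frame with columns `species`, `family`, `copies`
#'   (string over `{a, b}`, e.g. `"ab"`, `"a"`), and logical
#'   `clupeocephalan`.
#' @return List: `genes` (the informative subset, same columns),
#'   `n_sequences`, `n_families` (distinct families among kept genes).
#' @export
informative_filter <- function(query_genes, retention) {
  stopifnot(all(c("gene_id", "family") %in% names(query_genes)),
            all(c("species", "family", "copies", "clupeocephalan")
                %in% names(retention)))
  unknown <- setdiff(query_genes$family, retention$family)
  if (length(unknown))
    stop("family not present in retention table: ",
         paste(unknown, collapse = ", "))
  rr <- retention[retention$clupeocephalan, , drop = FALSE]
  has_both <- vapply(query_genes$family, function(f) {
    cp <- tolower(rr$copies[rr$family == f])
    any(grepl("a", cp) & grepl("b", cp))
  }, logical(1))
  kept <- query_genes[has_both, , drop = FALSE]
  rownames(kept) <- NULL
  list(genes = kept,
       n_sequences = nrow(kept),
       n_families = length(unique(kept$family)))
}

#' Read a retention table from TSV
#'
#' Columns `species`, `family`, `copies`, `clupeocephalan`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_retention <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$clupeocephalan <- as.logical(tab$clupeocephalan)
  tab
}

#' Bundled Hox informative-filter fixture
#'
#' A teleost Hox exemplar: 26 orthology-informative genes (five clusters, 22
#' gene families, physical order preserved) together with a *synthetic*
#' retention table consistent with them: every informative family has both
#' "a" and "b" copies in at least one duplicated species, and a few extra
#' families are included whose "b" copy is retained only outside the
#' duplicated group (so the filter drops them).
#'
#' @return List with data.frames `query_genes` (`gene_id`, `cluster`,
#'   `position`, `family`) and `retention` (see [informative_filter()]).
#' @export
hox_informative_fixture <- function() {
  qg <- utils::read.table(
    system.file("extdata", "hox_informative_genes.tsv", package = "wgdortho"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  rt <- read_retention(
    system.file("extdata", "hox_retention_synthetic.tsv",
                package = "wgdortho"))
  list(query_genes = qg, retention = rt)
}

#' Per-gene homology verdict
#'
#' The best hypothesis is the one with the maximal total log-likelihood; the
#' confidence grade counts how many of the two alternatives the AU test
#' rejects at `alpha`: both = `"confident"`, one = `"supported"`, none =
#' `"ambiguous"`.
#'
#' @param hyps A [build_hypothesis_set()] result.
#' @param au An `"au_test"` object computed on the same gene.
#' @param alpha Significance level (default 0.05).
#' @param gene_id Optional identifier carried through.
#' @return Object of class `"gene_verdict"`: list with `gene_id`,
#'   `best_hypothesis`, `au_p` (named p-values), `rejected`, `confidence`.
#' @export
gene_verdict <- function(hyps, au, alpha = 0.05, gene_id = NA_character_) {
  ll <- hyps$logliks[c("A", "B", "O")]
  best <- names(which.max(ll))
  rejected <- au_adjudicate(au, alpha)
  others <- setdiff(c("A", "B", "O"), best)
  n_rej <- sum(others %in% rejected)
  confidence <- c("ambiguous", "supported", "confident")[n_rej + 1L]
  structure(list(gene_id = gene_id, best_hypothesis = best,
                 logliks = ll,
                 au_p = stats::setNames(au$table$p_au, au$table$topology),
                 rejected = rejected, confidence = confidence,
                 alpha = alpha),
            class = "gene_verdict")
}

#' @export
print.gene_verdict <- function(x, ...) {
  cat(sprintf("%s: best hypothesis %s (%s; AU rejects: %s)\n",
              if (is.na(x$gene_id)) "gene" else x$gene_id,
              x$best_hypothesis, x$confidence,
              if (length(x$rejected)) paste(x$rejected, collapse = ",")
              else "none"))
  invisible(x)
}

#' Cluster-level report
#'
#' Combines per-gene verdicts in physical order with the concatenation-level
#' AU test and site-signal summary.  `mixed` is true when the non-ambiguous
#' verdicts span at least two hypotheses; `interleave_count` counts adjacent
#' differing pairs within the non-ambiguous subsequence.  The cluster is
#' called a candidate tetralogy (2:2 homology with no 1:1 ortholog, the
#' signature of lineage-independent diploidization after a shared WGD) when
#' the verdicts are mixed *and* the concatenation either cannot reject two
#' or more hypotheses or shows trifurcating site signal.
#'
#' @param verdicts List of [gene_verdict()] objects in physical order.
#' @param concat_au Optional `"au_test"` for the concatenated cluster.
#' @param concat_slrp Optional [slrp_summary()] for the concatenation.
#' @param alpha Significance level used on `concat_au`.
#' @return Object of class `"cluster_report"`.
#' @export
cluster_report <- function(verdicts, concat_au = NULL, concat_slrp = NULL,
                           alpha = 0.05) {
  if (length(verdicts) == 0) stop("need at least one gene verdict")
  best <- vapply(verdicts, `[[`, character(1), "best_hypothesis")
  conf <- vapply(verdicts, `[[`, character(1), "confidence")
  informative <- best[conf != "ambiguous"]
  mixed <- length(unique(informative)) >= 2
  interleave_count <- if (length(informative) > 1)
    sum(informative[-1] != informative[-length(informative)]) else 0L
  tab <- sort(table(best), decreasing = TRUE)
  majority_class <- names(tab)[1]
  majority_fraction <- unname(tab[1]) / length(best)

  concat_rejected <- if (!is.null(concat_au))
    au_adjudicate(concat_au, alpha) else NULL
  concat_unrejected <- if (!is.null(concat_au))
    3L - length(concat_rejected) else NA_integer_
  trifurcation <- if (!is.null(concat_slrp)) concat_slrp$trifurcation else FALSE
  tetralogy_call <- mixed &&
    ((!is.null(concat_au) && concat_unrejected >= 2) || trifurcation)

  structure(list(verdicts = verdicts,
                 best_sequence = best,
                 confidence = conf,
                 mixed = mixed,
                 interleave_count = as.integer(interleave_count),
                 majority_class = majority_class,
                 majority_fraction = majority_fraction,
                 concat_au = concat_au,
                 concat_rejected = concat_rejected,
                 concat_slrp = concat_slrp,
                 trifurcation = trifurcation,
                 tetralogy_call = tetralogy_call,
                 alpha = alpha),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster report (", length(x$verdicts), " genes)\n", sep = "")
  cat("  verdicts:", paste(x$best_sequence, collapse = " "), "\n")
  cat("  confidence:", paste(substr(x$confidence, 1, 1), collapse = " "), "\n")
  cat(sprintf("  mixed: %s; interleave count: %d; majority: %s (%.2f)\n",
              x$mixed, x$interleave_count, x$majority_class,
              x$majority_fraction))
  if (!is.null(x$concat_au))
    cat("  concatenation AU rejects:",
        if (length(x$concat_rejected)) paste(x$concat_rejected, collapse = ",")
        else "none", "\n")
  if (!is.null(x$concat_slrp))
    cat("  concatenation signal:",
        if (x$trifurcation) "trifurcating" else "not trifurcating", "\n")
  cat("  tetralogy call:", x$tetralogy_call, "\n")
  invisible(x)
}

#' Summarise dN/dS ratios
#'
#' `omega = dN / dS` per branch; `dS = 0` with `dN > 0` is flagged
#' `INFINITE` (a boundary estimate, not evidence by itself), and
#' `dN = dS = 0` is flagged `UNDEFINED`.
#'
#' @param dN,dS Non-negative per-site substitution estimates (vectorised).
#' @param branch_id Optional branch labels.
#' @return data.frame of class `"selection_summary"` with columns
#'   `branch_id`, `dN`, `dS`, `omega`, `flag`
#'   (`"OK"`/`"INFINITE"`/`"UNDEFINED"`).
#' @export
omega_ratio <- function(dN, dS, branch_id = NULL) {
  if (any(dN < 0) || any(dS < 0)) stop("dN and dS must be non-negative")
  n <- max(length(dN), length(dS))
  dN <- rep_len(dN, n); dS <- rep_len(dS, n)
  if (is.null(branch_id)) branch_id <- paste0("branch", seq_len(n))
  omega <- ifelse(dS > 0, dN / dS, NA_real_)
  flag <- ifelse(dS > 0, "OK", ifelse(dN > 0, "INFINITE", "UNDEFINED"))
  out <- data.frame(branch_id = branch_id, dN = dN, dS = dS,
                    omega = omega, flag = flag)
  class(out) <- c("selection_summary", "data.frame")
  out
}
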
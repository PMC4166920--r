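# Constrained topology hypotheses.  A clade map assigns every taxon a role
# (A_CLADE, B_CLADE, OUTGROUP, QUERY, UNCONSTRAINED) and supplies a fixed
# backbone tree over the non-query taxa.  For each homology hypothesis the
# query is grafted onto every admissible backbone edge, branch lengths are
# re-optimised per placement, and the maximum-likelihood placement is kept:
#   A - query attaches inside (or on the stem of) the "a" duplicate clade;
#   B - likewise for the "b" clade;
#   O - strictly outside the smallest clade containing both duplicate clades
#       (its stem edge included: the query becomes sister to the whole
#       duplication clade).

CLADE_ROLES <- c("A_CLADE", "B_CLADE", "OUTGROUP", "QUERY", "UNCONSTRAINED")

#' Construct a clade map
#'
#' @param roles Named character vector mapping every taxon to one of
#'   `"A_CLADE"`, `"B_CLADE"`, `"OUTGROUP"`, `"QUERY"`, `"UNCONSTRAINED"`.
#'   At least two taxa are required in each of the A, B and outgroup clades
#'   and at least one query.
#' @param backbone An [ape::phylo] tree whose tips are exactly the non-query
#'   taxa.  It is (re)rooted on the outgroup clade; the A and B clades must
#'   each be monophyletic in it once unconstrained taxa are ignored.
#' @return Object of class `"clade_map"`.
#' @export
clade_map <- function(roles, backbone) {
  roles <- toupper(unlist(roles))
  if (is.null(names(roles)) || anyDuplicated(names(roles)))
    stop("roles must be a named vector with unique taxon names")
  bad <- setdiff(unique(roles), CLADE_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  a <- names(roles)[roles == "A_CLADE"]
  b <- names(roles)[roles == "B_CLADE"]
  o <- names(roles)[roles == "OUTGROUP"]
  q <- names(roles)[roles == "QUERY"]
  u <- names(roles)[roles == "UNCONSTRAINED"]
  if (length(a) < 2 || length(b) < 2 || length(o) < 2)
    stop("need at least two taxa in each of the A, B and outgroup clades")
  if (length(q) < 1) stop("need at least one query taxon")
  non_query <- c(a, b, o, u)
  if (!setequal(backbone$tip.label, non_query))
    stop("backbone tips must be exactly the non-query taxa")
  if (is.null(backbone$edge.length))
    backbone$edge.length <- rep(0.1, nrow(backbone$edge))
  rooted <- ape::root(backbone, outgroup = o, resolve.root = TRUE)
  if (!ape::is.binary(rooted)) rooted <- ape::multi2di(rooted)
  # grafting needs strictly positive edges (rooting can introduce zeros)
  rooted$edge.length[rooted$edge.length <= 0] <- 1e-6
  core <- if (length(u)) ape::drop.tip(rooted, u) else rooted
  for (cl in list(a, b)) {
    m <- ape::getMRCA(core, cl)
    if (!setequal(core$tip.label[phangorn::Descendants(core, m, "tips")[[1]]], cl))
      stop("clade {", paste(cl, collapse = ","),
           "} is not monophyletic in the backbone")
  }
  structure(list(a = a, b = b, outgroup = o, query = q, unconstrained = u,
                 roles = roles, backbone = rooted),
            class = "clade_map")
}

#' Read a clade map from a two-column TSV plus a backbone newick
#'
#' @param roles_path TSV with columns `taxon` and `role` (header optional if
#'   the first line parses as a role assignment).
#' @param backbone_path Newick file for the backbone tree.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(roles_path, backbone_path) {
  tab <- utils::read.table(roles_path, sep = "\t", header = FALSE,
                           col.names = c("taxon", "role"),
                           stringsAsFactors = FALSE)
  if (toupper(tab$role[1]) == "ROLE") tab <- tab[-1, , drop = FALSE]
  clade_map(stats::setNames(tab$role, tab$taxon), read_newick(backbone_path))
}

#' @export
print.clade_map <- function(x, ...) {
  cat("Clade map:",
      length(x$a), "A-clade,", length(x$b), "B-clade,",
      length(x$outgroup), "outgroup,", length(x$query), "query,",
      length(x$unconstrained), "unconstrained taxa\n")
  invisible(x)
}

# Edge rows of a rooted tree whose child node lies in the subtree of `node`
# (stem excluded); the stem edge is the row whose child is `node`.
subtree_edges <- function(tree, node) {
  desc <- phangorn::Descendants(tree, node, "all")
  which(tree$edge[, 2] %in% desc)
}
stem_edge <- function(tree, node) which(tree$edge[, 2] == node)

admissible_edges <- function(tree, cm, hypothesis,
                             query_tips = character(0)) {
  hypothesis <- match.arg(hypothesis, c("A", "B", "O", "U"))
  if (hypothesis == "U") {
    adm <- seq_len(nrow(tree$edge))
  } else if (hypothesis %in% c("A", "B")) {
    cl <- c(if (hypothesis == "A") cm$a else cm$b, query_tips)
    cl <- intersect(cl, tree$tip.label)
    m <- ape::getMRCA(tree, cl)
    if (is.null(m)) {  # single-tip "clade" (first of two independent queries)
      adm <- stem_edge(tree, match(cl, tree$tip.label))
    } else {
      adm <- c(subtree_edges(tree, m), stem_edge(tree, m))
    }
  } else {
    ab <- intersect(c(cm$a, cm$b, query_tips), tree$tip.label)
    m <- ape::getMRCA(tree, ab)
    adm <- setdiff(seq_len(nrow(tree$edge)), subtree_edges(tree, m))
  }
  # the two edges incident to a binary root are the same unrooted edge:
  # keep only the first admissible one
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  re <- which(tree$edge[, 1] == root)
  if (length(re) == 2 && all(re %in% adm)) adm <- setdiff(adm, re[2])
  sort(adm)
}

graft_query <- function(tree, edge_row, query, pendant = 0.1) {
  child <- tree$edge[edge_row, 2]
  pos <- max(tree$edge.length[edge_row] / 2, 1e-6)
  if (length(query) == 1) {
    phytools::bind.tip(tree, query, edge.length = pendant,
                       where = child, position = pos)
  } else {
    cherry <- ape::read.tree(text = paste0(
      "(", paste0(query, ":", pendant / 2, collapse = ","), "):", pendant, ";"))
    ape::bind.tree(tree, cherry, where = child, position = pos)
  }
}

#' Enumerate constrained query placements
#'
#' One candidate tree per admissible attachment edge of the rooted backbone.
#' For hypotheses A and B the admissible edges are the constrained clade's
#' subtree edges plus its stem (`2k - 1` edges for a clean binary clade of
#' `k` leaves); for hypothesis O they are every edge strictly outside the
#' smallest clade containing both duplicate clades, including that clade's
#' stem.  Unconstrained taxa stay at their fixed backbone positions and never
#' restrict the query.  Multiple query taxa are attached as a cherry
#' (`query_mode = "cherry"`, default) or placed one after the other on
#' independently enumerated admissible edges (`query_mode = "independent"`).
#'
#' @param cm A [clade_map()].
#' @param hypothesis `"A"`, `"B"`, `"O"`, or `"U"` (unconstrained: every
#'   backbone edge is admissible).
#' @param query_mode `"cherry"` or `"independent"`; ignored for a single
#'   query taxon.
#' @param pendant Initial pendant branch length for grafted query tips
#'   (re-optimised downstream).
#' @return List of rooted candidate trees, each containing all backbone taxa
#'   plus the query tip(s).
#' @export
enumerate_placements <- function(cm, hypothesis,
                                 query_mode = c("cherry", "independent"),
                                 pendant = 0.1) {
  query_mode <- match.arg(query_mode)
  bb <- cm$backbone
  adm <- admissible_edges(bb, cm, hypothesis)
  if (length(adm) == 0)
    stop("no admissible attachment edge for hypothesis ", hypothesis)
  if (length(cm$query) == 1 || query_mode == "cherry") {
    lapply(adm, function(e) graft_query(bb, e, cm$query, pendant))
  } else {
    out <- list()
    for (e in adm) {
      t1 <- graft_query(bb, e, cm$query[1], pendant)
      adm2 <- admissible_edges(t1, cm, hypothesis, query_tips = cm$query[1])
      for (e2 in adm2)
        out[[length(out) + 1L]] <- graft_query(t1, e2, cm$query[-1], pendant)
    }
    out
  }
}

#' Split-based constraint check
#'
#' Independent predicate verifying that a candidate tree satisfies its
#' hypothesis: after dropping unconstrained taxa there must be a bipartition
#' separating (hypothesis A) the A clade plus all query taxa, (B) the B clade
#' plus the queries, or (O) the combined A+B clade with no query inside, from
#' the remaining taxa.
#'
#' @param tree Candidate tree containing the query taxa.
#' @param cm A [clade_map()].
#' @param hypothesis `"A"`, `"B"` or `"O"`.
#' @return Logical.
#' @export
check_constraint <- function(tree, cm, hypothesis) {
  hypothesis <- match.arg(hypothesis, c("A", "B", "O"))
  tr <- if (length(cm$unconstrained))
    ape::drop.tip(tree, intersect(cm$unconstrained, tree$tip.label)) else tree
  grp <- switch(hypothesis,
                A = c(cm$a, intersect(cm$query, tr$tip.label)),
                B = c(cm$b, intersect(cm$query, tr$tip.label)),
                O = c(cm$a, cm$b))
  anchor <- setdiff(tr$tip.label, grp)[1]
  rt <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
  m <- ape::getMRCA(rt, grp)
  if (is.null(m)) return(length(grp) == 1)
  setequal(rt$tip.label[phangorn::Descendants(rt, m, "tips")[[1]]], grp)
}

#' Maximum-likelihood constrained placement
#'
#' Evaluates every admissible placement for one hypothesis, re-optimising
#' branch lengths per placement, and returns the placement with the maximum
#' total log-likelihood (ties broken by enumeration order).
#'
#' @inheritParams enumerate_placements
#' @param aln An [aa_alignment()] covering all taxa.
#' @param model A [substitution_model()].
#' @param ... Passed to [optimize_branch_lengths()].
#' @return List with `tree`, `loglik`, `site_logliks`, `n_placements` and
#'   `placement` (index of the winning candidate).
#' @export
best_constrained <- function(aln, cm, model = substitution_model(),
                             hypothesis = "A",
                             query_mode = c("cherry", "independent"), ...) {
  query_mode <- match.arg(query_mode)
  cands <- enumerate_placements(cm, hypothesis, query_mode)
  best <- NULL
  best_i <- NA_integer_
  for (i in seq_along(cands)) {
    fit <- optimize_branch_lengths(aln, cands[[i]], model, ...)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best_i <- i
    }
  }
  list(tree = best$tree, loglik = best$loglik,
       site_logliks = best$site_logliks,
       n_placements = length(cands), placement = best_i)
}

#' Build the full hypothesis set (A, B, O)
#'
#' Runs [best_constrained()] for the three homology hypotheses (optionally
#' plus an unconstrained best placement over every backbone edge) and collects
#' total and per-site log-likelihoods.
#'
#' @inheritParams best_constrained
#' @param include_unconstrained Also evaluate the unconstrained placement
#'   (`"U"`), best over all edges.
#' @return Object of class `"hypothesis_set"`: list with `hypotheses` (per
#'   hypothesis the [best_constrained()] result), `logliks`, and
#'   `site_logliks` (matrix, one row per hypothesis).
#' @export
build_hypothesis_set <- function(aln, cm, model = substitution_model(),
                                 include_unconstrained = FALSE,
                                 query_mode = c("cherry", "independent"),
                                 ...) {
  query_mode <- match.arg(query_mode)
  hyps <- c("A", "B", "O", if (include_unconstrained) "U")
  res <- lapply(hyps, function(h)
    best_constrained(aln, cm, model, h, query_mode = query_mode, ...))
  names(res) <- hyps
  sl <- do.call(rbind, lapply(res, `[[`, "site_logliks"))
  rownames(sl) <- hyps
  structure(list(hypotheses = res,
                 logliks = vapply(res, `[[`, numeric(1), "loglik"),
                 site_logliks = sl,
                 n_sites = ncol(sl)),
            class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("Constrained topology hypotheses (", x$n_sites, " sites):\n", sep = "")
  for (h in names(x$hypotheses))
    cat(sprintf("  %s: logL = %.3f (%d placements)\n", h,
                x$logliks[h], x$hypotheses[[h]]$n_placements))
  cat("  best:", names(which.max(x$logliks)), "\n")
  invisible(x)
}

#' Write per-hypothesis site log-likelihoods as TSV
#'
#' Long format: `topology_id`, `site_index` (0-based), `loglik`.
#'
#' @param hyps A [build_hypothesis_set()] result (or any matrix with
#'   hypothesis rownames).
#' @param path Output path.
#' @export
write_site_logliks <- function(hyps, path) {
  sl <- if (inherits(hyps, "hypothesis_set")) hyps$site_logliks else hyps
  df <- data.frame(topology_id = rep(rownames(sl), each = ncol(sl)),
                   site_index = rep(seq_len(ncol(sl)) - 1L, nrow(sl)),
                   loglik = as.vector(t(sl)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
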
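# Synthetic gene-cluster generator for post-WGD homology scenarios.
#
# Times are measured before present in arbitrary units.  A single WGD at
# `wgd_time` duplicates the locus; until a diploidization time the two
# homeologs recombine freely and are modelled as literally one lineage
# (complete homogenisation), so the realised divergence of the "a"/"b"
# copies dates to diploidization, not to the WGD itself.
#
#   Shared diploidization (truth A or B): homogenisation ceases at
#   `diploidization_time_shared`, before the query lineage speciates at
#   `speciation_time`; the query copy x is then a 1:1 ortholog of one
#   duplicate clade (A: inside the "a" clade; B: inside "b"), and copy y
#   (if retained) of the other.
#
#   Independent diploidization (truth O): both lineages keep homogenising
#   past the speciation; the query's copies stop at
#   `diploidization_time_query` and the duplicate clades' at
#   `diploidization_time_clupeo`, both more recent than the speciation.
#   The query copies form a cherry outside the combined ("a","b") clade -
#   their coalescent is separate from the other lineage's.  A truly
#   independent second WGD (`independent_wgd = TRUE`) produces the same
#   per-gene topology class; the two scenarios are indistinguishable gene
#   by gene.
#
#   Mosaic genes (truth MOSAIC): partial homogenisation, modelled as
#   non-overlapping tracts each following the tree of a different scenario.

#' Scenario configuration for the cluster simulator
#'
#' Defaults describe a cluster of physically linked, conserved amino-acid
#' genes in a taxon set with two post-WGD duplicate clades of three species,
#' two pre-WGD outgroups and one query lineage, at divergences deep enough
#' that the constrained-placement classifier faces a realistic (but solvable)
#' problem at a few hundred columns per gene.
#'
#' @param wgd_time Time of the whole-genome duplication (before present).
#' @param speciation_time Query-vs-duplicate-lineage split; `< wgd_time`.
#' @param diploidization_time_shared Shared homogenisation cessation, in
#'   `(speciation_time, wgd_time]`; used for truth-A/B genes.
#' @param diploidization_time_query,diploidization_time_clupeo Per-lineage
#'   cessation times, `< speciation_time`; used for truth-O genes.
#' @param independent_wgd Model the query's duplication as a second,
#'   lineage-specific WGD (same per-gene topology class as independent
#'   diploidization).
#' @param root_time Outgroup divergence, `> wgd_time`.
#' @param crown_a,crown_b,crown_outgroup Crown ages of the duplicate and
#'   outgroup clades.
#' @param n_genes Genes per cluster.
#' @param gene_length Alignment columns per gene.
#' @param labels True labels per gene (`"A"`, `"B"`, `"O"`, recycled to
#'   `n_genes`); genes named in `mosaic_spec` become `"MOSAIC"`.
#' @param mosaic_spec Optional named list (by gene index as character) of
#'   data.frames with columns `start_frac`, `end_frac`, `label`:
#'   non-overlapping tract fractions within `[0, 1]` and the scenario each
#'   tract follows.
#' @param taxa Named list with character vectors `outgroup`, `a`, `b` and
#'   `query` (the query's x and y copy labels, in that order).
#' @param drop_copy Drop the query's y copy from the output (the single-copy
#'   classification problem); default `TRUE`.
#' @param unconstrained Labels of optional extra lineages branching between
#'   the WGD and the query speciation (left unconstrained downstream).
#' @param rate_scale Expected substitutions per site per unit time.
#' @param model A [substitution_model()] used for sequence simulation.
#' @param seed Integer seed; every simulator draw derives from it.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(wgd_time = 1.0,
                            speciation_time = 0.6,
                            diploidization_time_shared = 0.85,
                            diploidization_time_query = 0.3,
                            diploidization_time_clupeo = 0.3,
                            independent_wgd = FALSE,
                            root_time = 1.3,
                            crown_a = 0.25, crown_b = 0.25,
                            crown_outgroup = 0.5,
                            n_genes = 9L,
                            gene_length = 300L,
                            labels = "A",
                            mosaic_spec = NULL,
                            taxa = list(outgroup = c("out1", "out2"),
                                        a = c("a1", "a2", "a3"),
                                        b = c("b1", "b2", "b3"),
                                        query = c("query_x", "query_y")),
                            drop_copy = TRUE,
                            unconstrained = character(0),
                            rate_scale = 0.5,
                            model = substitution_model(),
                            seed = 1L) {
  cfg <- list(wgd_time = wgd_time, speciation_time = speciation_time,
              diploidization_time_shared = diploidization_time_shared,
              diploidization_time_query = diploidization_time_query,
              diploidization_time_clupeo = diploidization_time_clupeo,
              independent_wgd = independent_wgd,
              root_time = root_time,
              crown_a = crown_a, crown_b = crown_b,
              crown_outgroup = crown_outgroup,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              labels = rep(toupper(labels), length.out = n_genes),
              mosaic_spec = mosaic_spec,
              taxa = taxa, drop_copy = drop_copy,
              unconstrained = unconstrained,
              rate_scale = rate_scale, model = model,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (!(speciation_time < wgd_time))
      stop("speciation_time must be earlier (smaller) than wgd_time")
    if (!(diploidization_time_shared > speciation_time &&
          diploidization_time_shared <= wgd_time))
      stop("diploidization_time_shared must lie in (speciation_time, wgd_time]")
    if (diploidization_time_query >= speciation_time ||
        diploidization_time_clupeo >= speciation_time)
      stop("per-lineage diploidization times must be more recent than ",
           "speciation_time")
    if (min(diploidization_time_query, diploidization_time_clupeo) <= 0)
      stop("diploidization times must be positive")
    if (root_time <= wgd_time) stop("root_time must predate wgd_time")
    if (crown_a >= speciation_time || crown_b >= speciation_time)
      stop("duplicate-clade crown ages must be more recent than speciation")
    if (crown_outgroup >= root_time) stop("crown_outgroup must be < root_time")
    if (!all(labels %in% c("A", "B", "O")))
      stop("labels must be A, B or O (mosaic genes via mosaic_spec)")
    if (length(taxa$query) < 1) stop("need at least one query copy label")
    if (rate_scale <= 0) stop("rate_scale must be positive")
    if (!is.null(mosaic_spec)) {
      for (ms in mosaic_spec) {
        ms <- ms[order(ms$start_frac), , drop = FALSE]
        if (any(ms$start_frac < 0) || any(ms$end_frac > 1) ||
            any(ms$end_frac <= ms$start_frac) ||
            any(ms$start_frac[-1] < ms$end_frac[-nrow(ms)]))
          stop("mosaic tracts must be non-overlapping fractions in [0, 1]")
        if (!all(toupper(ms$label) %in% c("A", "B", "O")))
          stop("mosaic tract labels must be A, B or O")
      }
    }
  })
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Post-WGD scenario:", x$n_genes, "genes x", x$gene_length, "columns\n")
  cat(sprintf("  WGD %.3g, speciation %.3g, shared diploidization %.3g,\n",
              x$wgd_time, x$speciation_time, x$diploidization_time_shared))
  cat(sprintf("  per-lineage diploidization %.3g (query) / %.3g (duplicates)%s\n",
              x$diploidization_time_query, x$diploidization_time_clupeo,
              if (x$independent_wgd) ", independent second WGD" else ""))
  cat("  true labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# newick fragment builders ---------------------------------------------------

# comb clade over `taxa` with crown age `crown`; returns list(text, height)
clade_nwk <- function(taxa, crown) {
  k <- length(taxa)
  if (k == 1) return(list(text = taxa, height = 0))
  node <- list(text = taxa[k], height = 0)
  for (i in rev(seq_len(k - 1)))   # ladder: deepest split at the crown age
    node <- join_nwk(list(text = taxa[i], height = 0), node,
                     crown * (k - i) / (k - 1))
  node
}

join_nwk <- function(n1, n2, height) {
  list(text = sprintf("(%s:%.10g,%s:%.10g)", n1$text, height - n1$height,
                      n2$text, height - n2$height),
       height = height)
}

#' Build the true gene tree for one scenario label
#'
#' Returns a fully resolved, time-ultrametric gene tree whose branch lengths
#' are time spans multiplied by `rate_scale`.  See the scenario descriptions
#' in [scenario_config()].
#'
#' @param config A [scenario_config()].
#' @param label `"A"`, `"B"` or `"O"`.
#' @return An [ape::phylo] tree over the configured taxa (query y copy
#'   omitted when `drop_copy` is set).
#' @export
make_gene_tree <- function(config, label = "A") {
  label <- match.arg(toupper(label), c("A", "B", "O"))
  tx <- config$taxa
  qx <- tx$query[1]
  qy <- if (length(tx$query) > 1 && !config$drop_copy) tx$query[2] else NULL
  a_cl <- clade_nwk(tx$a, config$crown_a)
  b_cl <- clade_nwk(tx$b, config$crown_b)
  o_cl <- clade_nwk(tx$outgroup, config$crown_outgroup)
  t_s <- config$speciation_time

  if (label %in% c("A", "B")) {
    t_d <- config$diploidization_time_shared
    if (label == "A") {
      x_side <- join_nwk(list(text = qx, height = 0), a_cl, t_s)
      y_side <- if (is.null(qy)) b_cl else
        join_nwk(list(text = qy, height = 0), b_cl, t_s)
    } else {
      x_side <- join_nwk(list(text = qx, height = 0), b_cl, t_s)
      y_side <- if (is.null(qy)) a_cl else
        join_nwk(list(text = qy, height = 0), a_cl, t_s)
    }
    x_side <- add_unconstrained(x_side, config$unconstrained,
                                lo = t_s, hi = t_d)
    ingroup <- join_nwk(x_side, y_side, t_d)
  } else {
    t_dq <- config$diploidization_time_query
    t_dc <- config$diploidization_time_clupeo
    q_cl <- if (is.null(qy)) list(text = qx, height = 0) else
      join_nwk(list(text = qx, height = 0),
               list(text = qy, height = 0), t_dq)
    dup_cl <- join_nwk(a_cl, b_cl, t_dc)
    dup_cl <- add_unconstrained(dup_cl, config$unconstrained,
                                lo = t_dc, hi = t_s)
    ingroup <- join_nwk(q_cl, dup_cl, t_s)
  }
  root <- join_nwk(ingroup, o_cl, config$root_time)
  tr <- ape::read.tree(text = paste0(root$text, ";"))
  tr$edge.length <- tr$edge.length * config$rate_scale
  tr
}

# attach extra free lineages on the stem between `lo` and `hi` (times)
add_unconstrained <- function(node, labels, lo, hi) {
  if (!length(labels)) return(node)
  times <- lo + (hi - lo) * seq_along(labels) / (length(labels) + 1)
  for (i in seq_along(labels))
    node <- join_nwk(node, list(text = labels[i], height = 0), times[i])
  node
}

gene_truth <- function(gene_id, label, trees, tracts = NULL, config) {
  list(gene_id = gene_id, true_label = label, gene_tree = trees,
       tracts = tracts,
       diploidization_times_used = if (label %in% c("A", "B"))
         c(shared = config$diploidization_time_shared)
       else c(query = config$diploidization_time_query,
              clupeo = config$diploidization_time_clupeo))
}

#' Simulate an alignment along a tree
#'
#' Standard Markov simulation: root states from the model's stationary
#' frequencies, sites i.i.d., a Gamma rate category (plus the invariant
#' class, which fixes the site's residue across all taxa) drawn per site.
#'
#' @param tree An [ape::phylo] tree with branch lengths >= 0.
#' @param model A [substitution_model()].
#' @param length Number of columns.
#' @return An [aa_alignment()], one row per leaf.  Uses the current RNG
#'   state; seed via `set.seed()` or [simulate_cluster()].
#' @export
simulate_gene <- function(tree, model = substitution_model(), length = 300L) {
  taxa <- tree$tip.label
  if (length == 0)
    return(aa_alignment(matrix(character(0), nrow = length(taxa), ncol = 0,
                               dimnames = list(taxa, NULL))))
  k <- length(model$rates)
  p_inv <- model$invariant_proportion
  cat_probs <- c(model$weights, if (p_inv > 0) p_inv)
  cat_idx <- sample.int(length(cat_probs), length, replace = TRUE,
                        prob = cat_probs)
  out <- matrix(NA_character_, length(taxa), length,
                dimnames = list(taxa, NULL))
  states <- aa_states()
  for (ci in unique(cat_idx)) {
    sites <- which(cat_idx == ci)
    if (p_inv > 0 && ci == length(cat_probs)) {
      # invariant class: one stationary draw per site, shared by all taxa
      s <- sample(states, length(sites), replace = TRUE,
                  prob = model$frequencies)
      out[, sites] <- matrix(s, length(taxa), length(sites), byrow = TRUE)
    } else {
      sim <- phangorn::simSeq(tree, l = length(sites), type = "AA",
                              bf = model$frequencies,
                              Q = model$exchangeabilities[
                                lower.tri(model$exchangeabilities)],
                              rate = model$rates[ci])
      m <- toupper(as.character(sim))
      out[, sites] <- m[taxa, , drop = FALSE]
    }
  }
  aa_alignment(out)
}

#' Simulate a gene cluster with ground truth
#'
#' Simulates `n_genes` alignments in physical order under the configured
#' scenario labels (mosaic genes tract-wise), recording the true gene
#' tree(s) and label per gene and a reproducibility manifest.  Identical
#' `(config, seed)` give identical output.
#'
#' @param config A [scenario_config()].
#' @return List of class `"cluster_sim"`: `alignments` (list of
#'   [aa_alignment()]), `truths` (per-gene truth records), `manifest`
#'   (data.frame: gene_id, true_label, realized times, seed), and the echoed
#'   `config`.
#' @export
simulate_cluster <- function(config) {
  validate_scenario_config(config)
  set.seed(config$seed)
  alignments <- vector("list", config$n_genes)
  truths <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%02d", g)
    ms <- config$mosaic_spec[[as.character(g)]]
    if (!is.null(ms)) {
      ms <- ms[order(ms$start_frac), , drop = FALSE]
      bounds <- unique(round(c(0, ms$start_frac, ms$end_frac, 1) *
                               config$gene_length))
      # tracts not covered by the list follow the gene's base label
      tract_lab <- character(0)
      tract_len <- integer(0)
      base <- config$labels[g]
      cuts <- sort(bounds)
      for (i in seq_len(length(cuts) - 1)) {
        mid <- (cuts[i] + cuts[i + 1]) / 2 / config$gene_length
        hit <- which(ms$start_frac <= mid & ms$end_frac > mid)
        tract_lab <- c(tract_lab,
                       if (length(hit)) toupper(ms$label[hit]) else base)
        tract_len <- c(tract_len, cuts[i + 1] - cuts[i])
      }
      keep <- tract_len > 0
      tract_lab <- tract_lab[keep]; tract_len <- tract_len[keep]
      trees <- lapply(tract_lab, function(l) make_gene_tree(config, l))
      parts <- mapply(function(tr, len) simulate_gene(tr, config$model, len),
                      trees, tract_len, SIMPLIFY = FALSE)
      aln <- do.call(cbind, lapply(parts, unclass))
      alignments[[g]] <- aa_alignment(aln)
      truths[[g]] <- gene_truth(gid, "MOSAIC", trees,
                                tracts = data.frame(label = tract_lab,
                                                    length = tract_len),
                                config = config)
    } else {
      lab <- config$labels[g]
      tr <- make_gene_tree(config, lab)
      alignments[[g]] <- simulate_gene(tr, config$model, config$gene_length)
      truths[[g]] <- gene_truth(gid, lab, tr, config = config)
    }
    names(alignments)[g] <- names(truths)[g] <- gid
  }
  manifest <- data.frame(
    gene_id = names(alignments),
    true_label = vapply(truths, `[[`, character(1), "true_label"),
    length = vapply(alignments, ncol, integer(1)),
    wgd_time = config$wgd_time,
    speciation_time = config$speciation_time,
    diploidization_time_shared = config$diploidization_time_shared,
    diploidization_time_query = config$diploidization_time_query,
    diploidization_time_clupeo = config$diploidization_time_clupeo,
    seed = config$seed,
    row.names = NULL)
  structure(list(alignments = alignments, truths = truths,
                 manifest = manifest, config = config),
            class = "cluster_sim")
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat("Simulated cluster:", length(x$alignments), "genes, truth [",
      paste(x$manifest$true_label, collapse = " "), "]\n")
  invisible(x)
}

#' Write a simulated cluster to disk
#'
#' One aligned FASTA and one newick per gene, a TSV manifest, and the
#' scenario configuration echoed as YAML.
#'
#' @param sim A [simulate_cluster()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cluster <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$alignments)) {
    write_fasta(sim$alignments[[g]], file.path(dir, paste0(g, ".fasta")))
    tr <- sim$truths[[g]]$gene_tree
    if (!inherits(tr, "phylo")) tr <- do.call(c, tr)   # mosaic: multiPhylo
    ape::write.tree(tr, file.path(dir, paste0(g, ".nwk")))
  }
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$model <- cfg$model$name
  yaml::write_yaml(unclass(cfg), file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Species backbone and clade map implied by a scenario
#'
#' The classifier's inputs for simulated data: the species backbone over the
#' non-query taxa (duplicate clades sister to each other, outgroups basal;
#' unconstrained lineages on the duplicate stem) and the role assignment.
#'
#' @param config A [scenario_config()].
#' @return A [clade_map()].
#' @export
scenario_clade_map <- function(config) {
  tx <- config$taxa
  a_cl <- clade_nwk(tx$a, config$crown_a)
  b_cl <- clade_nwk(tx$b, config$crown_b)
  o_cl <- clade_nwk(tx$outgroup, config$crown_outgroup)
  dup <- join_nwk(a_cl, b_cl, config$diploidization_time_shared)
  dup <- add_unconstrained(dup, config$unconstrained,
                           lo = config$diploidization_time_shared,
                           hi = config$wgd_time)
  root <- join_nwk(dup, o_cl, config$root_time)
  bb <- ape::read.tree(text = paste0(root$text, ";"))
  bb$edge.length <- bb$edge.length * config$rate_scale
  query <- if (config$drop_copy) tx$query[1] else tx$query
  roles <- c(stats::setNames(rep("A_CLADE", length(tx$a)), tx$a),
             stats::setNames(rep("B_CLADE", length(tx$b)), tx$b),
             stats::setNames(rep("OUTGROUP", length(tx$outgroup)), tx$outgroup),
             stats::setNames(rep("UNCONSTRAINED", length(config$unconstrained)),
                             config$unconstrained),
             stats::setNames(rep("QUERY", length(query)), query))
  clade_map(roles, bb)
}
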
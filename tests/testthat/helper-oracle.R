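# Independent likelihood oracle: exhaustive enumeration over all internal-node
# state assignments, with transition probabilities from a matrix exponential
# (Matrix::expm), sharing no code with the package's pruning engine.

poisson_expm <- function(t) {
  Q <- matrix(1 / 19, 20, 20)
  diag(Q) <- -1
  as.matrix(Matrix::expm(Q * t))
}

# site likelihoods by brute-force sum over internal-state assignments;
# tips must be unambiguous residues
oracle_site_lik <- function(tree, aln, t_prob = poisson_expm,
                            freqs = rep(1 / 20, 20)) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  internal <- root:(nt + tree$Nnode)
  Ps <- lapply(tree$edge.length, t_prob)
  combos <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(combos) <- as.character(internal)
  tip_idx <- apply(unclass(aln)[tree$tip.label, , drop = FALSE], 2,
                   match, table = aa_states())
  vapply(seq_len(ncol(aln)), function(s) {
    state_of <- function(node) {
      if (node <= nt) rep(tip_idx[node, s], nrow(combos))
      else combos[, as.character(node)]
    }
    w <- freqs[combos[, as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      ps <- state_of(tree$edge[e, 1])
      cs <- state_of(tree$edge[e, 2])
      w <- w * Ps[[e]][cbind(ps, cs)]
    }
    sum(w)
  }, numeric(1))
}

# gapless random alignment over random residues (no phylogenetic signal;
# used where only the likelihood definition is under test)
random_alignment <- function(taxa, n_sites) {
  aa_alignment(matrix(sample(aa_states(), length(taxa) * n_sites,
                             replace = TRUE),
                      length(taxa), n_sites,
                      dimnames = list(taxa, NULL)))
}

# small random binary tree with given tips and uniform branch lengths
random_tree <- function(n_tips, bl_range = c(0.05, 0.5), rooted = FALSE) {
  tr <- ape::rtree(n_tips, rooted = rooted)
  tr$edge.length <- stats::runif(nrow(tr$edge), bl_range[1], bl_range[2])
  tr
}
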
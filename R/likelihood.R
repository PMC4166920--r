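# Per-site log-likelihood engine: vectorised Felsenstein pruning over a
# discrete-Gamma (+ invariant sites) rate mixture, with per-site scaling to
# avoid underflow.  Branch-length optimisation on a fixed topology is
# delegated to phangorn's C implementation, with a coordinate-wise pure-R
# fallback for degenerate inputs (two taxa, median Gamma discretisation).

# Encode an alignment as a 20 x (nsites * ntaxa) tip partial-likelihood
# block list: for each taxon a 20 x n matrix, unit vectors for residues,
# ones for '-'/'X' (missing).
tip_partials <- function(aln, taxa) {
  states <- aa_states()
  lapply(taxa, function(tx) {
    s <- unclass(aln)[tx, ]
    m <- matrix(0, 20, length(s))
    idx <- match(s, states)
    known <- !is.na(idx)
    if (any(known)) m[cbind(idx[known], which(known))] <- 1
    m[, !known] <- 1
    m
  })
}

# One pruning pass at a single rate multiplier, rescaling each internal
# node's partials by their per-site maximum to avoid underflow.
prune_rate_scaled <- function(tree, partials, model, rate) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  nsite <- ncol(partials[[1]])
  L <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) L[[i]] <- partials[[i]]
  log_scale <- rep(0, nsite)
  edge <- tree$edge
  el <- tree$edge.length
  n_children <- tabulate(edge[, 1], nbins = n_tip + tree$Nnode)
  seen <- integer(n_tip + tree$Nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- transition_prob(model, el[e], rate)
    contrib <- P %*% L[[ch]]
    if (is.null(L[[par]])) L[[par]] <- contrib else L[[par]] <- L[[par]] * contrib
    seen[par] <- seen[par] + 1L
    if (seen[par] == n_children[par]) {
      mx <- apply(L[[par]], 2, max)
      pos <- mx > 0
      sc <- ifelse(pos, mx, 1)
      L[[par]] <- sweep(L[[par]], 2, sc, "/")
      log_scale <- log_scale + ifelse(pos, log(mx), -Inf)
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- colSums(model$frequencies * L[[root]])
  list(lik = lik, log_scale = log_scale)
}

#' Per-site log-likelihoods on a fixed tree
#'
#' Felsenstein pruning of an amino-acid alignment on a fixed topology with
#' fixed branch lengths, under a [substitution_model()].  The site likelihood
#' is the rate-mixture average
#' \deqn{L_s = p_{inv}\, I(\mathrm{constant}_s)\, \pi_{x_s} +
#'       \sum_c w_c L_s(r_c),}
#' where constant sites are judged on non-missing residues and `'-'`/`'X'`
#' contribute an uninformative partial vector.  An impossible site pattern
#' (probability 0, e.g. conflicting residues on a zero-length path) yields
#' `-Inf`.
#'
#' @param aln An [aa_alignment()]; must cover all tree leaf labels.
#' @param tree An [ape::phylo] tree with non-negative branch lengths.
#' @param model A [substitution_model()].
#' @return Numeric vector of natural-log site likelihoods (length
#'   `ncol(aln)`), each `<= 0` or `-Inf`.
#' @export
site_logliks <- function(aln, tree, model = substitution_model()) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  missing_tx <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing_tx))
    stop("taxa in tree absent from alignment: ",
         paste(missing_tx, collapse = ", "))
  nsite <- ncol(aln)
  if (nsite == 0) return(numeric(0))
  partials <- tip_partials(aln, tree$tip.label)

  per_cat <- lapply(model$rates, function(r) {
    pr <- prune_rate_scaled(tree, partials, model, r)
    ifelse(pr$lik > 0, log(pr$lik) + pr$log_scale, -Inf)
  })
  # log-sum-exp across Gamma categories and the invariant class
  terms <- mapply(function(lp, w) lp + log(w), per_cat, model$weights,
                  SIMPLIFY = FALSE)
  p_inv <- model$invariant_proportion
  if (p_inv > 0) {
    sub <- unclass(aln)[tree$tip.label, , drop = FALSE]
    inv_lp <- apply(sub, 2, function(col) {
      res <- col[!(col %in% c("-", "X"))]
      if (length(res) == 0) return(0)            # all-missing: sum(pi) = 1
      if (length(unique(res)) > 1L) return(-Inf) # variable: zero-rate lik 0
      log(model$frequencies[match(res[1], aa_states())])
    })
    terms <- c(terms, list(inv_lp + log(p_inv)))
  }
  M <- do.call(rbind, terms)
  mx <- apply(M, 2, max)
  out <- ifelse(is.finite(mx), mx + log(colSums(exp(sweep(M, 2, mx)))), -Inf)
  unname(out)
}

#' Total log-likelihood
#'
#' Sum of [site_logliks()]; `-Inf` if any site pattern is impossible.
#'
#' @inheritParams site_logliks
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(aln, tree, model = substitution_model()) {
  sum(site_logliks(aln, tree, model))
}

#' Optimise branch lengths on a fixed topology
#'
#' Maximises the alignment log-likelihood over branch lengths with the
#' topology held fixed.  The default engine is phangorn's
#' [phangorn::optim.pml()]; a coordinate-wise bracketed scalar search (Brent
#' via [stats::optimize()] per branch, cycled until the improvement falls
#' below `tol`) is used for two-taxon trees, median Gamma discretisation, or
#' on request.  Branch lengths are clamped to `[min_bl, max_bl]` and the
#' returned log-likelihood never falls below the starting value.
#'
#' @inheritParams site_logliks
#' @param tol Convergence tolerance in log-likelihood units (default 1e-6).
#' @param engine `"phangorn"` or `"coordinate"`.
#' @param min_bl,max_bl Branch-length clamps (defaults 1e-8 and 20).
#' @param max_rounds Maximum optimisation sweeps for the coordinate engine;
#'   non-convergence returns the best tree so far with a warning.
#' @return List with `tree` (optimised branch lengths), `loglik` (computed
#'   with [site_logliks()]), `site_logliks`, and `converged`.
#' @export
optimize_branch_lengths <- function(aln, tree, model = substitution_model(),
                                    tol = 1e-6,
                                    engine = c("phangorn", "coordinate"),
                                    min_bl = 1e-8, max_bl = 20,
                                    max_rounds = 50L) {
  engine <- match.arg(engine)
  if (length(tree$tip.label) < 3L || model$gamma_median) engine <- "coordinate"
  start_ll <- total_loglik(aln, tree, model)
  if (engine == "phangorn") {
    tr <- tree
    if (!ape::is.binary(tr) || ape::is.rooted(tr)) tr <- ape::unroot(tr)
    tr$edge.length <- pmin(pmax(tr$edge.length, min_bl), max_bl)
    dat <- as_phyDat(aln[tr$tip.label, , drop = FALSE])
    args <- phangorn_model_args(model)
    fit <- phangorn::pml(tr, dat, bf = args$bf, Q = args$Q, k = args$k,
                         shape = args$shape, inv = args$inv)
    fit <- suppressWarnings(phangorn::optim.pml(
      fit, optEdge = TRUE, optNni = FALSE,
      control = phangorn::pml.control(epsilon = tol, maxit = 25, trace = 0)))
    out_tree <- fit$tree
    out_tree$edge.length <- pmin(pmax(out_tree$edge.length, min_bl), max_bl)
    converged <- TRUE
  } else {
    out_tree <- tree
    out_tree$edge.length <- pmin(pmax(out_tree$edge.length, min_bl), max_bl)
    ll <- total_loglik(aln, out_tree, model)
    converged <- FALSE
    for (round in seq_len(max_rounds)) {
      ll_prev <- ll
      for (e in seq_along(out_tree$edge.length)) {
        f <- function(b) {
          tt <- out_tree
          tt$edge.length[e] <- b
          total_loglik(aln, tt, model)
        }
        op <- stats::optimize(f, c(min_bl, max_bl), maximum = TRUE,
                              tol = max(tol, 1e-8))
        if (op$objective > ll) {
          out_tree$edge.length[e] <- op$maximum
          ll <- op$objective
        }
      }
      if (ll - ll_prev < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("branch-length optimisation did not converge in ",
              max_rounds, " rounds; returning best tree so far")
  }
  sl <- site_logliks(aln, out_tree, model)
  ll <- sum(sl)
  if (is.finite(start_ll) && ll < start_ll) {
    # never return a worse tree than the input
    out_tree <- tree
    sl <- site_logliks(aln, out_tree, model)
    ll <- sum(sl)
  }
  list(tree = out_tree, loglik = ll, site_logliks = sl, converged = converged)
}
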
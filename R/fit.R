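# Headline per-gene fit: constrained hypotheses + AU test + site-signal
# decomposition, wrapped in one classed object.

#' Classify the homology of a query gene
#'
#' Fits the three constrained homology hypotheses (query inside the "a"
#' clade, inside the "b" clade, or outside both) by exhaustive placement on
#' the backbone, runs the AU test on the per-site log-likelihoods, decomposes
#' the site-wise signal, and issues a verdict.
#'
#' @param aln An [aa_alignment()] covering the backbone and query taxa.
#' @param cm A [clade_map()].
#' @param model A [substitution_model()].
#' @param alpha AU significance level (default 0.05).
#' @param n_replicates,scales RELL bootstrap settings (see
#'   [rell_bootstrap()]).
#' @param sd_multiplier Site-outlier threshold (see [classify_sites()]).
#' @param seed Optional seed for the bootstrap resampling.
#' @param gene_id Identifier carried into the verdict.
#' @param ... Passed to [build_hypothesis_set()].
#' @return Object of class `"homology_fit"`: list with `hypotheses`
#'   (a [build_hypothesis_set()] result), `au`, `deltas` (classified
#'   [delta_table][classify_sites()]), `slrp` ([slrp_summary()]), and
#'   `verdict` ([gene_verdict()]).
#' @examples
#' cfg <- scenario_config(n_genes = 1, gene_length = 120, labels = "A",
#'                        seed = 7)
#' sim <- simulate_cluster(cfg)
#' fit <- classify_homology(sim$alignments[[1]], scenario_clade_map(cfg),
#'                          n_replicates = 200, seed = 7)
#' fit
#' @export
classify_homology <- function(aln, cm, model = substitution_model(),
                              alpha = 0.05, n_replicates = 1000L,
                              scales = seq(0.5, 1.4, by = 0.1),
                              sd_multiplier = 2, seed = NULL,
                              gene_id = NA_character_, ...) {
  hyps <- build_hypothesis_set(aln, cm, model, ...)
  au <- au_test(hyps, scales = scales, n_replicates = n_replicates,
                seed = seed)
  deltas <- classify_sites(compute_deltas(hyps), sd_multiplier = sd_multiplier)
  structure(list(hypotheses = hyps, au = au,
                 deltas = deltas, slrp = slrp_summary(deltas),
                 verdict = gene_verdict(hyps, au, alpha, gene_id = gene_id),
                 alpha = alpha, n_sites = hyps$n_sites,
                 call = match.call()),
            class = "homology_fit")
}

#' @export
print.homology_fit <- function(x, ...) {
  v <- x$verdict
  cat("Post-WGD homology fit (", x$n_sites, " sites)\n", sep = "")
  cat(sprintf("  best hypothesis: %s (%s)\n", v$best_hypothesis,
              v$confidence))
  p <- v$au_p[c("A", "B", "O")]
  cat(sprintf("  AU p-values: A = %.3g, B = %.3g, O = %.3g\n",
              p["A"], p["B"], p["O"]))
  invisible(x)
}

#' @export
summary.homology_fit <- function(object, ...) {
  print(object)
  print(object$hypotheses)
  print(object$au)
  print(object$slrp)
  invisible(object)
}

#' @export
logLik.homology_fit <- function(object, ...) {
  ll <- max(object$hypotheses$logliks)
  attr(ll, "df") <- NA_integer_
  class(ll) <- "logLik"
  ll
}

#' @export
plot.homology_fit <- function(x, ...) plot(x$deltas, ...)
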
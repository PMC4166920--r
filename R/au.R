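# Approximately unbiased (AU) topology test from per-site log-likelihoods.
# Multiscale RELL bootstrap: at each scale r, round(r * n) sites are resampled
# with replacement and each topology's resampled total log-likelihood is
# compared; its bootstrap proportion BP_r is the fraction of replicates it
# wins (argmax ties split uniformly at random).  The signed distance d and
# curvature c of the boundary are then estimated by weighted least squares on
# the probit scale,
#     qnorm(1 - BP_r) = d * sqrt(r) + c / sqrt(r),
# with binomial-variance weights, and p_AU = 1 - pnorm(d - c).

#' Multiscale RELL bootstrap proportions
#'
#' @param site_logliks Matrix of per-site log-likelihoods, one row per
#'   topology (rownames kept), identical sites per row.  A
#'   [build_hypothesis_set()] object may be passed directly.
#' @param scales Bootstrap scale factors (default `seq(0.5, 1.4, 0.1)`; at
#'   least 3 are required downstream).
#' @param n_replicates Replicates per scale (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @param by_partition Optional partition data.frame (`gene`, `start`, `end`,
#'   0-based half-open): resample whole genes as blocks instead of sites.
#' @return Matrix of bootstrap proportions (topologies x scales, columns
#'   named by scale), each column summing to 1, with `n_replicates` and
#'   `scales` attached as attributes.
#' @export
rell_bootstrap <- function(site_logliks, scales = seq(0.5, 1.4, by = 0.1),
                           n_replicates = 1000L, seed = NULL,
                           by_partition = NULL) {
  if (inherits(site_logliks, "hypothesis_set"))
    site_logliks <- site_logliks$site_logliks
  sl <- as.matrix(site_logliks)
  if (nrow(sl) < 2) stop("need at least 2 topologies")
  if (ncol(sl) < 2) stop("need at least 2 sites")
  if (any(scales <= 0)) stop("scales must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(by_partition)) {
    # collapse sites to per-gene blocks; block totals are resampled
    sl <- do.call(cbind, lapply(seq_len(nrow(by_partition)), function(i) {
      cols <- (by_partition$start[i] + 1L):by_partition$end[i]
      rowSums(sl[, cols, drop = FALSE])
    }))
  }
  n <- ncol(sl)
  k <- nrow(sl)
  bp <- matrix(NA_real_, k, length(scales),
               dimnames = list(rownames(sl), format(scales)))
  for (j in seq_along(scales)) {
    m <- max(1L, round(scales[j] * n))
    counts <- stats::rmultinom(n_replicates, m, rep(1 / n, n))
    totals <- sl %*% counts                       # k x n_replicates
    win <- max.col(t(totals), ties.method = "random")
    bp[, j] <- tabulate(win, nbins = k) / n_replicates
  }
  attr(bp, "n_replicates") <- n_replicates
  attr(bp, "scales") <- scales
  bp
}

#' Fit the AU curve and compute p-values
#'
#' @param bp Bootstrap-proportion matrix from [rell_bootstrap()].
#' @param scales Scale factors (taken from `bp`'s attribute if present).
#' @param n_replicates Replicates per scale (idem).
#' @param bp_clamp Minimum BP used on the probit scale (default
#'   `1 / (2 * n_replicates)`), preventing infinite quantiles.
#' @return Object of class `"au_test"`: a data.frame (`topology`, `p_au`,
#'   `d`, `c`, `fit_rss`, `degenerate`) plus the BP table.  When every BP of
#'   a topology lies at a clamp bound on the same side, the fit is flagged
#'   `degenerate` and `p_au` is pinned near the corresponding bound.
#' @export
fit_au <- function(bp, scales = attr(bp, "scales"),
                   n_replicates = attr(bp, "n_replicates"),
                   bp_clamp = NULL) {
  if (is.null(scales) || length(scales) < 3)
    stop("need at least 3 scales to fit the AU curve")
  if (is.null(n_replicates)) stop("n_replicates unknown")
  if (is.null(bp_clamp)) bp_clamp <- 1 / (2 * n_replicates)
  sq <- sqrt(scales)
  X <- cbind(d = sq, c = 1 / sq)
  res <- lapply(rownames(bp), function(tp) {
    raw <- bp[tp, ]
    degenerate <- all(raw <= bp_clamp) || all(raw >= 1 - bp_clamp)
    b <- pmin(pmax(raw, bp_clamp), 1 - bp_clamp)
    z <- stats::qnorm(1 - b)
    w <- n_replicates * stats::dnorm(z)^2 / (b * (1 - b))
    fit <- stats::lm.wfit(X, z, w)
    d <- unname(fit$coefficients["d"])
    cc <- unname(fit$coefficients["c"])
    p <- 1 - stats::pnorm(d - cc)
    if (degenerate) {
      # every BP saturates on one side: the curve is out of reach and the
      # p-value is pinned to the corresponding bound at clamp precision
      p <- if (all(raw >= 1 - bp_clamp)) 1 - bp_clamp else bp_clamp
    }
    data.frame(topology = tp, p_au = p, d = d, c = cc,
               fit_rss = sum(w * fit$residuals^2),
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- out$topology
  structure(list(table = out, bp = bp, scales = scales,
                 n_replicates = n_replicates, bp_clamp = bp_clamp),
            class = "au_test")
}

#' Run the AU test from site log-likelihoods
#'
#' Convenience wrapper: [rell_bootstrap()] then [fit_au()].  Total
#' log-likelihoods per topology are recorded for downstream adjudication.
#'
#' @inheritParams rell_bootstrap
#' @param ... Passed to [rell_bootstrap()].
#' @return An `"au_test"` object (see [fit_au()]).
#' @export
au_test <- function(site_logliks, ...) {
  if (inherits(site_logliks, "hypothesis_set"))
    site_logliks <- site_logliks$site_logliks
  out <- fit_au(rell_bootstrap(site_logliks, ...))
  out$total_logliks <- rowSums(as.matrix(site_logliks))
  out
}

#' @export
print.au_test <- function(x, ...) {
  cat("Approximately unbiased test (", x$n_replicates,
      " RELL replicates x ", length(x$scales), " scales):\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %s: p_AU = %.4g  (d = %.3f, c = %.3f)%s\n",
                tab$topology[i], tab$p_au[i], tab$d[i], tab$c[i],
                if (tab$degenerate[i]) "  [degenerate fit]" else ""))
  invisible(x)
}

#' Adjudicate hypotheses from AU p-values
#'
#' Topologies with `p_au < alpha` are rejected.  The test is never allowed to
#' reject everything: if all p-values fall below `alpha` the
#' maximum-likelihood topology is retained with a warning.
#'
#' @param au An `"au_test"` object (from [au_test()] or [fit_au()]).
#' @param alpha Significance level (default 0.05).
#' @param logliks Optional named total log-likelihoods (taken from the
#'   object when produced by [au_test()]).
#' @return Character vector of rejected topology names (possibly empty).
#' @export
au_adjudicate <- function(au, alpha = 0.05, logliks = au$total_logliks) {
  p <- stats::setNames(au$table$p_au, au$table$topology)
  rejected <- names(p)[p < alpha]
  if (length(rejected) == length(p) && length(p) > 0) {
    if (is.null(logliks))
      stop("all topologies rejected and no log-likelihoods to fall back on")
    keep <- names(which.max(logliks[names(p)]))
    warning("AU test rejected every topology at alpha = ", alpha,
            "; retaining the maximum-likelihood topology ", keep)
    rejected <- setdiff(names(p), keep)
  }
  rejected
}

#' Write AU results as TSV
#'
#' @param au An `"au_test"` object.
#' @param path Output path for the per-topology table; the BP-by-scale table
#'   goes to `paste0(path, ".bp")` .
#' @export
write_au <- function(au, path) {
  utils::write.table(au$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bp <- data.frame(topology = rownames(au$bp), au$bp, check.names = FALSE)
  utils::write.table(bp, paste0(path, ".bp"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
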
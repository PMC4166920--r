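# Site-likelihood-ratio decomposition across the three homology hypotheses.
# Per site s with log-likelihoods l_A, l_B, l_O:
#   delta1 = 2 (l_A - l_B),  delta2 = 2 (l_A - l_O),  delta3 = 2 (l_B - l_O),
# so delta2 = delta1 + delta3 identically.  Sites are coloured when a delta
# lies more than `sd_multiplier` standard deviations from the axis centre,
# and the joint sign pattern assigns the site to the topology it supports.

#' Per-site likelihood-ratio decomposition
#'
#' @param site_logliks Matrix of per-site log-likelihoods with rows named
#'   `"A"`, `"B"`, `"O"` (e.g. from [build_hypothesis_set()], which can be
#'   passed directly), identical site sets per row.
#' @return Object of class `"delta_table"`: a data.frame with `site`
#'   (1-based), `delta1`, `delta2`, `delta3` and an unset `class` column.
#' @export
compute_deltas <- function(site_logliks) {
  if (inherits(site_logliks, "hypothesis_set"))
    site_logliks <- site_logliks$site_logliks
  sl <- as.matrix(site_logliks)
  need <- c("A", "B", "O")
  if (!all(need %in% rownames(sl)))
    stop("site_logliks must have rows A, B and O")
  sl <- sl[need, , drop = FALSE]
  if (any(!is.finite(sl)))
    stop("non-finite site log-likelihoods; deltas undefined")
  dt <- data.frame(site = seq_len(ncol(sl)),
                   delta1 = 2 * (sl["A", ] - sl["B", ]),
                   delta2 = 2 * (sl["A", ] - sl["O", ]),
                   delta3 = 2 * (sl["B", ] - sl["O", ]),
                   class = NA_character_)
  class(dt) <- c("delta_table", "data.frame")
  dt
}

#' Classify outlier sites by the k-SD rule
#'
#' On each axis a site is *extreme* when its delta lies more than
#' `sd_multiplier` standard deviations from the axis centre (the axis mean by
#' default, or zero).  The joint pattern maps to the supported topology:
#' A = extreme-positive on delta1 and delta2; B = extreme-negative on delta1
#' and extreme-positive on delta3; O = extreme-negative on delta2 and delta3.
#' Sites matching no rule are `"none"`; a site matching more than one rule
#' (impossible under the default signed rules, kept for safety) is
#' `"conflict"`.
#'
#' @param dt A [compute_deltas()] table with at least 2 sites.
#' @param sd_multiplier Threshold multiplier (default 2).
#' @param center `"mean"` (default) or `"zero"`.
#' @return The table with `class` filled in; axis means/SDs and the rule
#'   configuration are attached as attributes.
#' @export
classify_sites <- function(dt, sd_multiplier = 2, center = c("mean", "zero")) {
  center <- match.arg(center)
  if (nrow(dt) < 2) stop("need at least 2 sites to estimate an SD")
  d <- as.matrix(dt[, c("delta1", "delta2", "delta3")])
  mu <- if (center == "mean") colMeans(d) else c(0, 0, 0)
  sdv <- apply(d, 2, stats::sd)
  z <- sweep(d, 2, mu)
  pos <- sweep(z, 2, sd_multiplier * sdv, ">")
  neg <- sweep(z, 2, -sd_multiplier * sdv, "<")
  isA <- pos[, 1] & pos[, 2]
  isB <- neg[, 1] & pos[, 3]
  isO <- neg[, 2] & neg[, 3]
  n_rules <- isA + isB + isO
  cls <- rep("none", nrow(dt))
  cls[isA] <- "A"
  cls[isB] <- "B"
  cls[isO] <- "O"
  cls[n_rules > 1] <- "conflict"
  dt$class <- cls
  attr(dt, "axis_mean") <- mu
  attr(dt, "axis_sd") <- sdv
  attr(dt, "sd_multiplier") <- sd_multiplier
  attr(dt, "center") <- center
  dt
}

#' Summarise a classified delta table
#'
#' @param dt A classified [delta_table][classify_sites()].
#' @return Object of class `"slrp_summary"`: per-class site counts, a
#'   `trifurcation` flag (at least two of the A/B/O classes non-empty among
#'   coloured sites) and a `unidirectional` flag (exactly one class
#'   non-empty).
#' @export
slrp_summary <- function(dt) {
  if (all(is.na(dt$class))) stop("delta table is not classified yet")
  counts <- vapply(c("A", "B", "O", "none", "conflict"),
                   function(k) sum(dt$class == k, na.rm = TRUE), integer(1))
  nonempty <- sum(counts[c("A", "B", "O")] > 0)
  structure(list(counts = counts,
                 trifurcation = nonempty >= 2,
                 unidirectional = nonempty == 1,
                 n_sites = nrow(dt)),
            class = "slrp_summary")
}

#' @export
print.slrp_summary <- function(x, ...) {
  cat("Site-likelihood-ratio summary (", x$n_sites, " sites):\n", sep = "")
  cat("  supporting A:", x$counts["A"], " B:", x$counts["B"],
      " O:", x$counts["O"], " uncoloured:", x$counts["none"], "\n")
  if (x$trifurcation)
    cat("  conflicting (trifurcating) signal: coloured sites support",
        sum(x$counts[c("A", "B", "O")] > 0), "different topologies\n")
  else if (x$unidirectional)
    cat("  unidirectional signal: all coloured sites support",
        names(which(x$counts[c("A", "B", "O")] > 0)), "\n")
  else cat("  no coloured sites\n")
  invisible(x)
}

#' Export a delta table as TSV (and optionally plot it)
#'
#' @param dt A [delta_table][compute_deltas()].
#' @param path Output TSV path (`site`, `delta1`, `delta2`, `delta3`,
#'   `class`).
#' @param plot_path Optional path for a PNG of the three pairwise panels.
#' @export
export_slrp <- function(dt, path, plot_path = NULL) {
  utils::write.table(as.data.frame(dt)[, c("site", "delta1", "delta2",
                                           "delta3", "class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 1200, height = 420)
    on.exit(grDevices::dev.off())
    plot(dt)
  }
  invisible(path)
}

#' Read a delta-table TSV back
#'
#' @param path TSV written by [export_slrp()].
#' @return A `"delta_table"` data.frame.
#' @export
read_slrp <- function(path) {
  dt <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(dt) <- c("delta_table", "data.frame")
  dt
}

#' Plot a delta table
#'
#' Three pairwise scatter panels of the per-site likelihood-ratio axes.
#' Coloured by supported topology: A red, B blue, O green; unclassified
#' sites grey.
#'
#' @param x A [delta_table][compute_deltas()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.delta_table <- function(x, ...) {
  cols <- c(A = "red", B = "blue", O = "green3",
            none = "grey70", conflict = "black")
  cl <- ifelse(is.na(x$class), "none", x$class)
  op <- graphics::par(mfrow = c(1, 3), pty = "s")
  on.exit(graphics::par(op))
  panels <- list(c("delta1", "delta2"), c("delta1", "delta3"),
                 c("delta2", "delta3"))
  for (p in panels) {
    graphics::plot(x[[p[1]]], x[[p[2]]], col = cols[cl], pch = 19,
                   xlab = p[1], ylab = p[2], ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(x)
}
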
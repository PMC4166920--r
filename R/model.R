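# Amino-acid substitution model: reversible GTR-style rate matrix built from a
# symmetric exchangeability matrix and stationary frequencies, with discrete
# Gamma + invariant-sites rate heterogeneity.  State order is the PAML/phangorn
# amino-acid order so exchangeability files and phyDat encodings agree.

#' Amino-acid state alphabet (PAML order)
#'
#' The 20 amino-acid one-letter codes in the order used by PAML-format rate
#' matrix files and by [phangorn::phyDat()] amino-acid objects.
#'
#' @return Character vector of length 20.
#' @export
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct a reversible amino-acid substitution model
#'
#' Builds the instantaneous rate matrix Q with entries
#' \eqn{Q_{ij} = s_{ij} \pi_j} (i != j) from a symmetric exchangeability
#' matrix \eqn{s} and stationary frequencies \eqn{\pi}, normalised so that the
#' expected substitution rate at stationarity is 1 (branch lengths are then
#' expected substitutions per site).  Rate heterogeneity across sites uses a
#' discrete Gamma distribution (default 4 categories, mean-of-category
#' discretisation) optionally mixed with a proportion of invariant sites; the
#' combined category rates always have mean 1.
#'
#' @param exchangeabilities Either the string `"poisson"` (all
#'   exchangeabilities equal; with uniform frequencies this is the 20-state
#'   equal-rates model with closed-form transition probabilities), a symmetric
#'   20x20 numeric matrix of non-negative exchangeabilities (diagonal
#'   ignored), or the path to a PAML-format rate file (lower-triangle rows
#'   followed by 20 frequencies, as distributed for LG/WAG and relatives).
#' @param frequencies Stationary frequencies (20-vector summing to 1).
#'   Defaults to uniform for `"poisson"`, to the file's frequencies for a PAML
#'   file, and to uniform otherwise.
#' @param gamma_shape Shape parameter alpha of the Gamma rate distribution, or
#'   `NULL` (no Gamma heterogeneity).
#' @param n_rate_categories Number of discrete Gamma categories (default 4).
#' @param invariant_proportion Proportion of invariant sites, in `[0, 1)`.
#' @param gamma_median Use median- instead of mean-of-category discretisation.
#'
#' @return An object of class `"substitution_model"`: a list with the
#'   normalised `Q`, `frequencies`, the symmetric-eigendecomposition used for
#'   transition probabilities, and the mixture `rates`/`weights`.
#' @seealso [transition_prob()], [site_logliks()]
#' @export
substitution_model <- function(exchangeabilities = "poisson",
                               frequencies = NULL,
                               gamma_shape = NULL,
                               n_rate_categories = 4L,
                               invariant_proportion = 0,
                               gamma_median = FALSE) {
  n <- 20L
  if (is.character(exchangeabilities) && length(exchangeabilities) == 1L) {
    if (identical(tolower(exchangeabilities), "poisson")) {
      S <- matrix(1, n, n)
      name <- "poisson"
    } else {
      paml <- read_paml_matrix(exchangeabilities)
      S <- paml$exchangeabilities
      if (is.null(frequencies)) frequencies <- paml$frequencies
      name <- basename(exchangeabilities)
    }
  } else {
    S <- as.matrix(exchangeabilities)
    name <- "custom"
  }
  if (!all(dim(S) == c(n, n)))
    stop("exchangeability matrix must be 20x20")
  if (any(S[lower.tri(S)] < 0))
    stop("exchangeabilities must be non-negative")
  if (max(abs(S - t(S))) > 1e-10)
    stop("exchangeability matrix must be symmetric")
  diag(S) <- 0

  if (is.null(frequencies)) frequencies <- rep(1 / n, n)
  pi <- as.numeric(frequencies)
  if (length(pi) != n || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must be 20 positive values summing to 1")
  pi <- pi / sum(pi)

  Q <- S * rep(pi, each = n)        # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # expected rate at stationarity
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q <- Q / mu

  # symmetric similarity transform: B = D Q D^-1 with D = diag(sqrt(pi))
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2               # enforce symmetry against roundoff
  eig <- eigen(B, symmetric = TRUE)

  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be > 0")
  if (invariant_proportion < 0 || invariant_proportion >= 1)
    stop("invariant_proportion must be in [0, 1)")
  p_inv <- invariant_proportion

  if (is.null(gamma_shape)) {
    g <- 1
  } else {
    g <- discrete_gamma_rates(gamma_shape, n_rate_categories,
                              median = gamma_median)
  }
  # scale so the full mixture (including the zero-rate invariant class)
  # has mean rate 1
  if (p_inv > 0) g <- g / (1 - p_inv)
  rates <- g
  weights <- rep((1 - p_inv) / length(g), length(g))

  structure(list(
    name = name,
    Q = Q,
    exchangeabilities = S,
    frequencies = pi,
    eigenvalues = eig$values,
    # P(t) = right %*% diag(exp(lambda t)) %*% left, with
    # right = D^-1 U, left = U' D, D = diag(sqrt(pi))
    right = eig$vectors / sq,
    left = t(eig$vectors) * rep(sq, each = n),
    gamma_shape = gamma_shape,
    n_rate_categories = if (is.null(gamma_shape)) 1L else as.integer(n_rate_categories),
    gamma_median = gamma_median,
    invariant_proportion = p_inv,
    rates = rates,
    weights = weights
  ), class = "substitution_model")
}

#' Discrete Gamma category rates
#'
#' Mean rate of each of `k` equal-probability Gamma categories with shape
#' `alpha`, normalised to mean 1 (the standard discretisation); with
#' `median = TRUE` the category medians are used, rescaled to mean 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @param median Use median- instead of mean-of-category discretisation.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k, median = FALSE) {
  k <- as.integer(k)
  if (k < 1L) stop("n_rate_categories must be >= 1")
  if (k == 1L) return(1)
  if (median) {
    q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = alpha, rate = alpha)
    return(q / mean(q))
  }
  b <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- stats::pgamma(c(b, Inf), shape = alpha + 1, rate = alpha)
  k * diff(c(0, p))
}

#' Transition probability matrix
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site); must be >= 0.
#' @param rate Rate multiplier (e.g. a Gamma category rate).
#' @return 20x20 matrix with rows summing to 1; exactly the identity at
#'   `t * rate == 0`.
#' @export
transition_prob <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  tt <- t * rate
  if (tt == 0) return(diag(20))
  P <- model$right %*% (exp(model$eigenvalues * tt) * model$left)
  P[P < 0] <- 0
  P
}

#' Read a PAML-format amino-acid rate file
#'
#' Parses the standard empirical-matrix text layout: 19 rows of the lower
#' triangle of the symmetric exchangeability matrix followed by the 20
#' stationary frequencies, all whitespace-separated, states in PAML order
#' (see [aa_states()]).
#'
#' @param path File path.
#' @return List with `exchangeabilities` (symmetric 20x20, zero diagonal) and
#'   `frequencies` (length 20).
#' @export
read_paml_matrix <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(x) < 210)
    stop("PAML matrix file must contain 190 exchangeabilities + 20 frequencies")
  S <- matrix(0, 20, 20)
  idx <- 1L
  for (i in 2:20) {
    S[i, seq_len(i - 1L)] <- x[idx:(idx + i - 2L)]
    idx <- idx + i - 1L
  }
  S <- S + t(S)
  f <- x[idx:(idx + 19L)]
  list(exchangeabilities = S, frequencies = f / sum(f))
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("  frequencies:",
      if (max(abs(x$frequencies - 0.05)) < 1e-12) "uniform" else "empirical",
      "\n")
  if (is.null(x$gamma_shape)) {
    cat("  rate heterogeneity: none")
  } else {
    cat(sprintf("  discrete Gamma: alpha = %g, %d categories (%s)",
                x$gamma_shape, x$n_rate_categories,
                if (x$gamma_median) "median" else "mean"))
  }
  if (x$invariant_proportion > 0)
    cat(sprintf(" + p_inv = %g", x$invariant_proportion))
  cat("\n")
  invisible(x)
}

# Arguments for phangorn::pml matching this model (used by the branch-length
# optimiser).  phangorn scales Gamma rates by 1/(1-inv) exactly as above.
phangorn_model_args <- function(model) {
  if (model$gamma_median)
    stop("median Gamma discretisation is not supported by the phangorn engine")
  list(bf = model$frequencies,
       Q = model$exchangeabilities[lower.tri(model$exchangeabilities)],
       k = model$n_rate_categories,
       shape = if (is.null(model$gamma_shape)) 1 else model$gamma_shape,
       inv = model$invariant_proportion)
}
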
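test_that("site likelihoods agree with boundary closed forms", {
  m <- substitution_model()
  tr <- ape::read.tree(text = "(A:0,B:0);")
  same <- aa_alignment(matrix(c("A", "A"), 2, 1,
                              dimnames = list(c("A", "B"), NULL)))
  expect_equal(site_logliks(same, tr, m), log(1 / 20), tolerance = 1e-12)
  diff <- aa_alignment(matrix(c("A", "R"), 2, 1,
                              dimnames = list(c("A", "B"), NULL)))
  expect_identical(site_logliks(diff, tr, m), -Inf)
  # missing data is uninformative: a gap row contributes nothing
  gap <- aa_alignment(matrix(c("A", "-"), 2, 1,
                             dimnames = list(c("A", "B"), NULL)))
  expect_equal(site_logliks(gap, tr, m), log(1 / 20), tolerance = 1e-12)
})

test_that("pruning equals exhaustive internal-state enumeration on small trees", {
  m <- substitution_model()
  set.seed(31)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    tr <- random_tree(n, rooted = FALSE)
    aln <- random_alignment(tr$tip.label, 10)
    mine <- site_logliks(aln, tr, m)
    oracle <- log(oracle_site_lik(tr, aln))
    worst <- max(worst, max(abs(mine - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("pattern probabilities on a 3-leaf tree sum to one", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.35,C:0.1);")
  pats <- expand.grid(aa_states(), aa_states(), aa_states(),
                      stringsAsFactors = FALSE)
  mat <- t(as.matrix(pats))
  rownames(mat) <- c("A", "B", "C")
  aln <- aa_alignment(mat)
  for (m in list(substitution_model(),
                 substitution_model(gamma_shape = 0.7,
                                    invariant_proportion = 0.2))) {
    expect_equal(sum(exp(site_logliks(aln, tr, m))), 1, tolerance = 1e-8)
  }
})

test_that("total log-likelihood is additive over sites and reroot-invariant", {
  m <- substitution_model(gamma_shape = 1.2)
  set.seed(17)
  tr <- random_tree(6, rooted = TRUE)
  aln <- random_alignment(tr$tip.label, 25)
  sl <- site_logliks(aln, tr, m)
  expect_equal(total_loglik(aln, tr, m), sum(sl), tolerance = 1e-12)
  one <- aa_alignment(unclass(aln)[, 1, drop = FALSE])
  expect_equal(total_loglik(one, tr, m), sl[1], tolerance = 1e-12)
  doubled <- aa_alignment(cbind(unclass(aln), unclass(aln)))
  expect_equal(total_loglik(doubled, tr, m), 2 * sum(sl), tolerance = 1e-9)
  # pulley principle: rerooting anywhere leaves the likelihood unchanged
  base <- total_loglik(aln, ape::unroot(tr), m)
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(total_loglik(aln, rr, m), base, tolerance = 1e-9)
  }
})

test_that("large Gamma shape converges to the single-rate likelihood", {
  set.seed(5)
  tr <- random_tree(5)
  aln <- random_alignment(tr$tip.label, 30)
  flat <- total_loglik(aln, tr, substitution_model())
  gaps <- vapply(c(10, 100, 1000), function(a)
    abs(total_loglik(aln, tr, substitution_model(gamma_shape = a)) - flat),
    numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.05)
})

test_that("input validation catches bad taxa and branch lengths", {
  m <- substitution_model()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- random_alignment(c("A", "C"), 5)
  expect_error(site_logliks(aln, tr, m), "absent from alignment")
  tr$edge.length[1] <- -0.1
  expect_error(site_logliks(random_alignment(c("A", "B"), 5), tr, m),
               "negative")
})

test_that("branch-length optimisation recovers the closed-form two-taxon MLE", {
  m <- substitution_model()
  # 100 sites, 5 differing: MLE distance -(19/20) log(1 - 20/19 * 0.05)
  mat <- matrix("A", 2, 100, dimnames = list(c("s1", "s2"), NULL))
  mat[2, 1:5] <- "R"
  aln <- aa_alignment(mat)
  tr <- ape::read.tree(text = "(s1:0.2,s2:0.2);")
  fit <- optimize_branch_lengths(aln, tr, m, tol = 1e-8)
  expect_equal(sum(fit$tree$edge.length),
               -(19 / 20) * log(1 - (20 / 19) * 0.05), tolerance = 1e-4)
  # identical sequences: distance driven to the lower clamp
  mat[2, ] <- mat[1, ]
  fit0 <- optimize_branch_lengths(aa_alignment(mat), tr, m)
  expect_lt(sum(fit0$tree$edge.length), 1e-5)
})

test_that("optimisation never decreases the log-likelihood", {
  m <- substitution_model()
  set.seed(41)
  tr <- random_tree(5, rooted = FALSE)
  true_aln <- simulate_gene(tr, m, 200)
  start <- tr
  start$edge.length <- rep(0.3, nrow(tr$edge))
  before <- total_loglik(true_aln, start, m)
  for (engine in c("phangorn", "coordinate")) {
    fit <- optimize_branch_lengths(true_aln, start, m, engine = engine)
    expect_gte(fit$loglik, before)
    expect_equal(fit$loglik, sum(fit$site_logliks), tolerance = 1e-9)
  }
  # the two engines agree on the optimum
  f1 <- optimize_branch_lengths(true_aln, start, m, engine = "phangorn")
  f2 <- optimize_branch_lengths(true_aln, start, m, engine = "coordinate",
                                tol = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-2)
})
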
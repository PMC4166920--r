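test_that("omega ratios reproduce the worked example and flag edge cases", {
  s <- omega_ratio(0.183, 0.128)
  expect_equal(round(s$omega, 2), 1.43)
  expect_equal(s$flag, "OK")
  expect_equal(omega_ratio(0.01, 0)$flag, "INFINITE")
  expect_true(is.na(omega_ratio(0.01, 0)$omega))
  expect_equal(omega_ratio(0, 0)$flag, "UNDEFINED")
  expect_equal(omega_ratio(0.5, 0.5)$omega, 1)
  expect_error(omega_ratio(-0.1, 0.2), "non-negative")
  v <- omega_ratio(c(0.183, 0.014), c(0.128, 0.002),
                   branch_id = c("x", "y"))
  expect_equal(nrow(v), 2)
})

test_that("the informative filter keeps both-copy families and drops the rest", {
  fx <- hox_informative_fixture()
  res <- informative_filter(fx$query_genes, fx$retention)
  expect_equal(res$n_sequences, 26)
  expect_equal(res$n_families, 22)
  # a family with only "a" copies in every duplicated species is dropped,
  # even when a non-duplicated species retains both
  extra <- rbind(fx$query_genes,
                 data.frame(gene_id = "hoxb13x", cluster = "hoxbx",
                            position = 0, family = "b13"))
  res2 <- informative_filter(extra, fx$retention)
  expect_equal(res2$n_sequences, 26)
  expect_false("hoxb13x" %in% res2$genes$gene_id)
  # filter is idempotent and a subset of its input
  res3 <- informative_filter(res$genes, fx$retention)
  expect_identical(res3$genes$gene_id, res$genes$gene_id)
  expect_error(informative_filter(
    data.frame(gene_id = "g", family = "nope"), fx$retention),
    "not present")
})

fake_hyps <- function(lA, lB, lO, n = 10) {
  sl <- rbind(A = rep(lA / n, n), B = rep(lB / n, n), O = rep(lO / n, n))
  structure(list(logliks = c(A = lA, B = lB, O = lO), site_logliks = sl,
                 n_sites = n),
            class = "hypothesis_set")
}
fake_au <- function(p) {
  structure(list(table = data.frame(topology = names(p), p_au = unname(p),
                                    row.names = names(p)),
                 total_logliks = c(A = -10, B = -20, O = -30)),
            class = "au_test")
}

test_that("gene verdicts grade confidence by the number of AU rejections", {
  v <- gene_verdict(fake_hyps(-100, -150, -160),
                    fake_au(c(A = 0.9, B = 0.001, O = 0.01)), gene_id = "g1")
  expect_equal(v$best_hypothesis, "A")
  expect_equal(v$confidence, "confident")
  v2 <- gene_verdict(fake_hyps(-100, -150, -160),
                     fake_au(c(A = 0.9, B = 0.02, O = 0.4)))
  expect_equal(v2$confidence, "supported")
  v3 <- gene_verdict(fake_hyps(-100, -99, -160),
                     fake_au(c(A = 0.5, B = 0.6, O = 0.2)))
  expect_equal(v3$best_hypothesis, "B")
  expect_equal(v3$confidence, "ambiguous")
})

test_that("cluster reports capture interleaving, majority and tetralogy calls", {
  seq_best <- c("O", "B", "A", "O", "O", "A", "A", "A", "A")
  verdicts <- lapply(seq_along(seq_best), function(i) {
    lab <- seq_best[i]
    ll <- c(A = -110, B = -110, O = -110); ll[lab] <- -100
    gene_verdict(fake_hyps(unname(ll["A"]), unname(ll["B"]),
                           unname(ll["O"])),
                 fake_au(stats::setNames(ifelse(c("A", "B", "O") == lab,
                                                0.9, 0.01),
                                         c("A", "B", "O"))),
                 gene_id = paste0("g", i))
  })
  slrp_tri <- structure(list(counts = c(A = 5, B = 4, O = 6, none = 100,
                                        conflict = 0),
                             trifurcation = TRUE, unidirectional = FALSE,
                             n_sites = 115),
                        class = "slrp_summary")
  rep1 <- cluster_report(verdicts, concat_slrp = slrp_tri)
  expect_true(rep1$mixed)
  expect_equal(rep1$majority_class, "A")
  expect_equal(rep1$majority_fraction, 5 / 9)
  expect_equal(rep1$best_sequence, seq_best, ignore_attr = TRUE)
  expect_true(rep1$tetralogy_call)
  expect_equal(rep1$interleave_count,
               sum(seq_best[-1] != seq_best[-9]))
  # all-A cluster with a decisive concatenation: no tetralogy
  allA <- lapply(1:5, function(i)
    gene_verdict(fake_hyps(-100, -150, -160),
                 fake_au(c(A = 0.9, B = 0.001, O = 0.01))))
  rep2 <- cluster_report(allA,
                         concat_au = fake_au(c(A = 0.95, B = 1e-4, O = 2e-4)))
  expect_false(rep2$mixed)
  expect_false(rep2$tetralogy_call)
  expect_equal(rep2$interleave_count, 0L)
  # mixed verdicts with an undecided concatenation: tetralogy
  rep3 <- cluster_report(verdicts,
                         concat_au = fake_au(c(A = 0.4, B = 0.3, O = 0.01)))
  expect_true(rep3$tetralogy_call)
  # single verdict
  rep4 <- cluster_report(verdicts[3])
  expect_equal(rep4$interleave_count, 0L)
  expect_false(rep4$mixed)
  expect_error(cluster_report(list()), "at least one")
})

test_that("ambiguous verdicts are excluded from the mixed/interleave signal", {
  mk <- function(lab, conf_p) {
    ll <- c(A = -110, B = -110, O = -110); ll[lab] <- -100
    p <- stats::setNames(rep(conf_p, 3), c("A", "B", "O"))
    if (conf_p < 0.05) p[lab] <- 0.9
    gene_verdict(fake_hyps(unname(ll["A"]), unname(ll["B"]),
                           unname(ll["O"])), fake_au(p))
  }
  # only one non-ambiguous class: not mixed despite differing argmaxes
  verdicts <- list(mk("A", 0.01), mk("O", 0.5), mk("A", 0.01))
  rep <- cluster_report(verdicts)
  expect_false(rep$mixed)
  expect_equal(rep$interleave_count, 0L)
})
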
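make_cm <- function(n_a = 3, n_b = 3, n_o = 2, query = "q",
                    unconstrained = character(0)) {
  cfg <- scenario_config(taxa = list(outgroup = paste0("o", seq_len(n_o)),
                                     a = paste0("a", seq_len(n_a)),
                                     b = paste0("b", seq_len(n_b)),
                                     query = query),
                         drop_copy = length(query) == 1,
                         unconstrained = unconstrained)
  scenario_clade_map(cfg)
}

test_that("admissible edge counts follow the 2k-1 rule for constrained clades", {
  cm <- make_cm(n_a = 3, n_b = 2)
  expect_length(enumerate_placements(cm, "A"), 2 * 3 - 1)
  expect_length(enumerate_placements(cm, "B"), 2 * 2 - 1)
  cm4 <- make_cm(n_a = 4)
  expect_length(enumerate_placements(cm4, "A"), 2 * 4 - 1)
})

test_that("hypothesis-O placements exclude the interior of the duplication clade", {
  cm <- make_cm()
  ab <- c(cm$a, cm$b)
  for (tr in enumerate_placements(cm, "O")) {
    # the duplicate clades stay jointly monophyletic without the query
    expect_true(check_constraint(tr, cm, "O"))
    rt <- ape::root(tr, outgroup = "q", resolve.root = TRUE)
    mr <- ape::getMRCA(rt, ab)
    tips <- rt$tip.label[phangorn::Descendants(rt, mr, "tips")[[1]]]
    expect_setequal(tips, ab)
  }
})

test_that("every enumerated placement satisfies its split-based constraint", {
  cm <- make_cm(unconstrained = "eel")
  for (h in c("A", "B", "O")) {
    trees <- enumerate_placements(cm, h)
    expect_true(all(vapply(trees, check_constraint, logical(1),
                           cm = cm, hypothesis = h)))
    # and each tree violates at least one of the other constraints
    others <- setdiff(c("A", "B", "O"), h)
    cross <- vapply(trees, function(tr)
      any(vapply(others, function(o) check_constraint(tr, cm, o),
                 logical(1))), logical(1))
    expect_false(any(cross))
  }
})

test_that("two query copies can be attached as a cherry or independently", {
  cm <- make_cm(query = c("qx", "qy"))
  cherry <- enumerate_placements(cm, "A", query_mode = "cherry")
  expect_length(cherry, 5)
  expect_true(all(vapply(cherry, function(tr) {
    rt <- ape::root(tr, outgroup = "o1", resolve.root = TRUE)
    mr <- ape::getMRCA(rt, c("qx", "qy"))
    setequal(rt$tip.label[phangorn::Descendants(rt, mr, "tips")[[1]]],
             c("qx", "qy"))
  }, logical(1))))
  indep <- enumerate_placements(cm, "A", query_mode = "independent")
  expect_gt(length(indep), length(cherry))
  expect_true(all(vapply(indep, check_constraint, logical(1),
                         cm = cm, hypothesis = "A")))
})

test_that("constrained search recovers the generating placement and accounts", {
  cfg <- scenario_config(n_genes = 1, gene_length = 400, labels = "A",
                         seed = 13)
  sim <- simulate_cluster(cfg)
  cm <- scenario_clade_map(cfg)
  res <- best_constrained(sim$alignments[[1]], cm, cfg$model, "A")
  expect_equal(res$n_placements, length(enumerate_placements(cm, "A")))
  expect_true(check_constraint(res$tree, cm, "A"))
  expect_length(res$site_logliks, 400)
  expect_equal(res$loglik, sum(res$site_logliks), tolerance = 1e-9)
})

test_that("hypothesis set orders nested searches correctly", {
  cfg <- scenario_config(n_genes = 1, gene_length = 150, labels = "O",
                         seed = 23)
  sim <- simulate_cluster(cfg)
  cm <- scenario_clade_map(cfg)
  hs <- build_hypothesis_set(sim$alignments[[1]], cm, cfg$model,
                             include_unconstrained = TRUE)
  # constrained optima can never beat the unconstrained best
  expect_gte(hs$logliks["U"] + 1e-6, max(hs$logliks[c("A", "B", "O")]))
  expect_equal(unname(rowSums(hs$site_logliks)), unname(hs$logliks),
               tolerance = 1e-9)
  expect_equal(names(which.max(hs$logliks[c("A", "B", "O")])), "O")
})

test_that("a single-site alignment is degenerate but legal", {
  cfg <- scenario_config(n_genes = 1, gene_length = 1, labels = "A", seed = 3)
  sim <- simulate_cluster(cfg)
  cm <- scenario_clade_map(cfg)
  res <- best_constrained(sim$alignments[[1]], cm, cfg$model, "A")
  expect_s3_class(res$tree, "phylo")
  expect_length(res$site_logliks, 1)
})

test_that("clade map validation rejects malformed inputs", {
  bb <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,(o1:1,o2:1):1);")
  roles <- c(a1 = "A_CLADE", a2 = "A_CLADE", b1 = "B_CLADE", b2 = "B_CLADE",
             o1 = "OUTGROUP", o2 = "OUTGROUP", q = "QUERY")
  expect_s3_class(clade_map(roles, bb), "clade_map")
  expect_error(clade_map(c(roles, extra = "OUTGROUP"), bb),
               "backbone tips")
  expect_error(clade_map(c(roles, z = "WEIRD"), bb), "unknown role")
  too_few <- roles; too_few["b2"] <- "OUTGROUP"
  expect_error(clade_map(too_few, bb), "at least two")
  # non-monophyletic A clade
  bb2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1,(o1:1,o2:1):1);")
  expect_error(clade_map(roles, bb2), "not monophyletic")
})

test_that("clade map TSV + newick round-trips", {
  cm <- make_cm()
  dir <- withr::local_tempdir()
  roles_path <- file.path(dir, "roles.tsv")
  write.table(data.frame(taxon = names(cm$roles), role = cm$roles),
              roles_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  bb_path <- file.path(dir, "bb.nwk")
  write_newick(cm$backbone, bb_path)
  cm2 <- read_clade_map(roles_path, bb_path)
  expect_setequal(cm2$a, cm$a)
  expect_setequal(cm2$query, cm$query)
})
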
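test_that("scenario configuration enforces the time ordering", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(speciation_time = 1.2), "speciation_time")
  expect_error(scenario_config(diploidization_time_shared = 0.5),
               "diploidization_time_shared")  # must predate speciation (0.6)
  expect_error(scenario_config(diploidization_time_query = 0.7),
               "more recent than")
  expect_error(scenario_config(root_time = 0.9), "root_time")
  expect_error(scenario_config(
    mosaic_spec = list(`1` = data.frame(start_frac = c(0, 0.4),
                                        end_frac = c(0.5, 0.9),
                                        label = c("A", "O")))),
    "non-overlapping")
})

test_that("gene trees realise the defining clade structure of each label", {
  cfg <- scenario_config(drop_copy = FALSE)
  is_clade <- function(tr, tips, anchor) {
    rt <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
    m <- ape::getMRCA(rt, tips)
    setequal(rt$tip.label[phangorn::Descendants(rt, m, "tips")[[1]]], tips)
  }
  trA <- make_gene_tree(cfg, "A")
  expect_true(is_clade(trA, c("query_x", cfg$taxa$a), "out1"))
  expect_true(is_clade(trA, c("query_y", cfg$taxa$b), "out1"))
  trB <- make_gene_tree(cfg, "B")
  expect_true(is_clade(trB, c("query_x", cfg$taxa$b), "out1"))
  trO <- make_gene_tree(cfg, "O")
  # independent diploidization: the query copies coalesce with each other,
  # outside the combined duplicate clade
  expect_true(is_clade(trO, c("query_x", "query_y"), "out1"))
  expect_true(is_clade(trO, c(cfg$taxa$a, cfg$taxa$b), "out1"))
  # trees are ultrametric in time (constant rate scaling preserves this)
  expect_true(ape::is.ultrametric(trA, tol = 1e-8))
  # branch lengths are rate_scale times the time spans
  cfg2 <- scenario_config(rate_scale = 1)
  expect_equal(max(ape::node.depth.edgelength(make_gene_tree(cfg2, "A"))),
               cfg2$root_time, tolerance = 1e-9)
})

test_that("an independent second WGD is topologically indistinguishable per gene", {
  cfg1 <- scenario_config(drop_copy = FALSE)
  cfg2 <- scenario_config(drop_copy = FALSE, independent_wgd = TRUE)
  t1 <- make_gene_tree(cfg1, "O")
  t2 <- make_gene_tree(cfg2, "O")
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("sequence simulation honours boundary cases and the closed form", {
  m <- substitution_model()
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  set.seed(8)
  aln <- simulate_gene(tr, m, 50)
  expect_true(all(apply(unclass(aln), 2, function(x) length(unique(x)) == 1)))
  empty <- simulate_gene(tr, m, 0)
  expect_equal(dim(empty), c(4L, 0L))
  expect_setequal(rownames(empty), c("a", "b", "c", "d"))
  # one branch of length t: P(differ) = (19/20)(1 - exp(-20 t / 19))
  t <- 0.3
  two <- ape::read.tree(text = sprintf("(x:%g,y:0);", t))
  set.seed(123)
  big <- simulate_gene(two, m, 10000)
  p_hat <- mean(unclass(big)["x", ] != unclass(big)["y", ])
  p_exp <- (19 / 20) * (1 - exp(-20 * t / 19))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
})

test_that("cluster simulation is deterministic and labels the manifest", {
  cfg <- scenario_config(n_genes = 3, gene_length = 60,
                         labels = c("A", "O", "B"), seed = 99)
  s1 <- simulate_cluster(cfg)
  s2 <- simulate_cluster(cfg)
  expect_identical(lapply(s1$alignments, unclass),
                   lapply(s2$alignments, unclass))
  expect_equal(s1$manifest$true_label, c("A", "O", "B"))
  expect_equal(s1$manifest$seed, rep(99L, 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cluster(s1, d1); write_cluster(s2, d2)
  for (f in c("gene01.fasta", "gene02.fasta", "gene03.fasta", "manifest.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "scenario.yaml")))
})

test_that("mosaic genes carry tract-wise trees and the MOSAIC truth label", {
  cfg <- scenario_config(n_genes = 2, gene_length = 100, labels = "A",
                         mosaic_spec = list(
                           `2` = data.frame(start_frac = c(0, 0.5),
                                            end_frac = c(0.5, 1),
                                            label = c("A", "O"))),
                         seed = 15)
  sim <- simulate_cluster(cfg)
  expect_equal(sim$truths[[1]]$true_label, "A")
  expect_equal(sim$truths[[2]]$true_label, "MOSAIC")
  expect_equal(sim$truths[[2]]$tracts$label, c("A", "O"))
  expect_equal(sum(sim$truths[[2]]$tracts$length), 100)
  expect_equal(ncol(sim$alignments[[2]]), 100)
})

test_that("pairwise identity decreases with path length on the tree", {
  cfg <- scenario_config(n_genes = 1, gene_length = 300, labels = "A",
                         seed = 55)
  tr <- make_gene_tree(cfg, "A")
  dists <- ape::cophenetic.phylo(tr)
  agree <- 0
  for (rep in 1:20) {
    set.seed(1000 + rep)
    aln <- simulate_gene(tr, cfg$model, 300)
    taxa <- rownames(aln)
    pairs <- t(combn(taxa, 2))
    ident <- apply(pairs, 1, function(p)
      mean(unclass(aln)[p[1], ] == unclass(aln)[p[2], ]))
    pd <- dists[cbind(pairs[, 1], pairs[, 2])]
    agree <- agree + (stats::cor(ident, pd, method = "spearman") < 0)
  }
  expect_gte(agree, 19)   # negative rank correlation in nearly every replicate
})

test_that("unconstrained extra lineages appear between WGD and speciation", {
  cfg <- scenario_config(unconstrained = "eel", drop_copy = TRUE)
  tr <- make_gene_tree(cfg, "A")
  expect_true("eel" %in% tr$tip.label)
  cm <- scenario_clade_map(cfg)
  expect_equal(cm$unconstrained, "eel")
  # the eel never restricts the query: placement counts unchanged
  expect_length(enumerate_placements(cm, "B"), 5)
})
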
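# Synthetic-data generator: stationarity, dropout, codon saturation,
# attraction scenario construction.

test_that("scenario validation and determinism", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  model <- substitution_model(ncat = 2)
  comp <- composition_cv1(rep(0.25, 4))
  expect_error(simulation_scenario(tree, comp, model, mode = "codon",
                                   gene_lengths = 10L), "divisible by 3")
  expect_error(simulation_scenario(tree, comp, model, dropout = 1), "dropout")

  sc <- simulation_scenario(tree, comp, model, gene_lengths = c(30L, 60L),
                            seed = 5)
  t1 <- simulate_alignment(sc)
  t2 <- simulate_alignment(sc)
  expect_identical(t1$genes$gene1$mat, t2$genes$gene1$mat)
  expect_equal(unname(t1$lengths), c(30L, 60L))
  t3 <- simulate_alignment(sc, seed = 6)
  expect_false(identical(t1$genes$gene1$mat, t3$genes$gene1$mat))
})

test_that("zero-length branches copy the root draw everywhere", {
  tree <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  sc <- simulation_scenario(tree, composition_cv1(c(.4, .1, .2, .3)),
                            substitution_model(ncat = 2),
                            gene_lengths = 50L, seed = 2)
  tab <- simulate_alignment(sc)
  m <- tab$genes$gene1$mat
  for (i in 2:4) expect_equal(unname(m[i, ]), unname(m[1, ]))
})

test_that("a long branch reaches its stationary composition", {
  tree <- ape::read.tree(text = "(A:0.01,B:25);")
  pi <- c(.4, .1, .2, .3)
  sc <- simulation_scenario(tree, composition_cv1(pi),
                            substitution_model(alpha = 5, ncat = 2),
                            gene_lengths = 10000L, seed = 3)
  m <- simulate_alignment(sc)$genes$gene1$mat
  counts <- table(factor(m["B", ], levels = c("A", "C", "G", "T")))
  gof <- sum((counts - 10000 * pi)^2 / (10000 * pi))
  expect_gt(pchisq(gof, df = 3, lower.tail = FALSE), 0.01)
})

test_that("dropout produces the expected missing fraction", {
  tree <- random_topology(paste0("t", 1:26), 0.1)
  sc <- simulation_scenario(tree, composition_cv1(rep(.25, 4)),
                            substitution_model(ncat = 1),
                            gene_lengths = rep(30L, 36), dropout = 0.095,
                            seed = 4)
  tab <- simulate_alignment(sc)
  frac <- mean(!tab$presence)
  se <- sqrt(0.095 * 0.905 / (36 * 26))
  expect_lt(abs(frac - 0.095), 4 * se)
})

test_that("synonymous saturation: third positions plateau, recoded distances grow", {
  model <- substitution_model(ncat = 1)
  tab <- build_degeneracy_table(1)
  dist_at <- function(t) {
    tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
    sc <- simulation_scenario(tree, composition_cv1(rep(.25, 4)), model,
                              mode = "codon", gene_lengths = 6000L,
                              omega_syn = 8, seed = 17)
    aln <- concatenate(simulate_alignment(sc))
    third <- seq(3, 6000, by = 3)
    d3 <- mean(aln$mat["A", third] != aln$mat["B", third])
    rec <- degen_recode(aln, tab)
    ddeg <- mean(rec$mat["A", ] != rec$mat["B", ])
    c(third = d3, degen = ddeg)
  }
  d_short <- dist_at(1.5)
  d_long <- dist_at(5)
  # third positions approach the 0.75 saturation plateau: the relative
  # increase is small, while the recoded (synonymous-free) divergence more
  # than doubles over the same branch-length range
  expect_gt(d_short[["third"]], 0.45)
  expect_lt((d_long[["third"]] - d_short[["third"]]) / d_short[["third"]],
            (d_long[["degen"]] - d_short[["degen"]]) / d_short[["degen"]])
  expect_gt(d_long[["degen"]], d_short[["degen"]] * 2)
})

test_that("attraction scenario builder records distinct target splits", {
  sc <- make_attraction_scenario(bias_strength = 0.8, seed = 1)
  expect_false(setequal(sc$true_clade, sc$attraction_clade))
  expect_true(all(sc$true_clade %in% sc$tree$tip.label))
  expect_error(make_attraction_scenario(bias_strength = 1.2), "bias_strength")

  # bias 0 reduces to a homogeneous scenario: all node vectors identical
  sc0 <- make_attraction_scenario(bias_strength = 0, seed = 1)
  pm <- sc0$comp$pimat
  expect_true(all(apply(pm, 2, function(x) diff(range(x))) < 1e-12))

  # grouped variant keeps group structure
  sc2 <- make_attraction_scenario(n_taxa_per_group = 2, bias_strength = 0.5)
  expect_length(sc2$tree$tip.label, 8)
  expect_length(sc2$true_clade, 4)
})

test_that("simulate-infer round trip recovers CV1 parameters", {
  tree <- ape::read.tree(text = "((A:0.15,B:0.2):0.08,(C:0.12,D:0.25):0.08);")
  true_pi <- c(.35, .15, .2, .3)
  sc <- simulation_scenario(tree, composition_cv1(true_pi),
                            substitution_model(alpha = 0.6, ncat = 4),
                            gene_lengths = 2000L, seed = 7)
  aln <- concatenate(simulate_alignment(sc))
  tr <- run_chain(aln, model_spec(substitution_model(ncat = 4), "CV1"),
                  n_iterations = 4000, sample_interval = 10, seed = 1)
  idx <- degenphy:::post_burnin_idx(tr, 0.25)
  pis <- do.call(rbind, lapply(tr$samples[idx], function(s) s$comps[1, ]))
  al <- sapply(tr$samples[idx], `[[`, "alpha")
  for (j in 1:4)
    expect_lt(abs(mean(pis[, j]) - true_pi[j]), 3 * sd(pis[, j]) + 0.01)
  expect_lt(abs(mean(al) - 0.6), 3 * sd(al) + 0.02)
})
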
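# Rate matrices, gamma discretisation, transition kernels and the pruning
# likelihood against independent oracles.

test_that("rate matrix construction: scaling, balance, JC limit", {
  R <- matrix(1, 4, 4); diag(R) <- 0
  Q <- build_rate_matrix(R, rep(0.25, 4))
  expect_equal(unname(Q[1, 2]), 1 / 3)
  expect_equal(unname(diag(Q)), rep(-1, 4))

  set.seed(1)
  for (i in 1:5) {
    Rr <- matrix(0, 4, 4)
    Rr[upper.tri(Rr)] <- rgamma(6, 1); Rr <- Rr + t(Rr)
    pi <- rgamma(4, 2); pi <- pi / sum(pi)
    Qr <- build_rate_matrix(Rr, pi)
    expect_equal(rowSums(Qr), rep(0, 4), tolerance = 1e-12)
    expect_equal(-sum(pi * diag(Qr)), 1, tolerance = 1e-12)
    expect_equal(pi * Qr, t(pi * Qr), tolerance = 1e-12) # detailed balance
  }
  expect_error(build_rate_matrix(R, c(0.5, 0.5, 0, 0)), "> 0")
})

test_that("transition probabilities match the JC closed form", {
  R <- matrix(1, 4, 4); diag(R) <- 0
  Q <- build_rate_matrix(R, rep(0.25, 4))
  expect_equal(transition_probabilities(Q, 0), diag(4))
  for (t in c(0.01, 0.1, 0.5, 2)) {
    P <- transition_probabilities(Q, t, pi = rep(0.25, 4))
    pii <- 0.25 + 0.75 * exp(-4 * t / 3)
    pij <- 0.25 - 0.25 * exp(-4 * t / 3)
    expect_lt(max(abs(diag(P) - pii)), 1e-10)
    expect_lt(abs(P[1, 2] - pij), 1e-10)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    # agreement between symmetric fast path and the general exponential
    expect_equal(P, transition_probabilities(Q, t), tolerance = 1e-10)
  }
  Plong <- transition_probabilities(Q, 500, pi = rep(0.25, 4))
  expect_equal(unname(Plong[1, ]), rep(0.25, 4), tolerance = 1e-9)
  expect_error(transition_probabilities(Q, Inf), "finite")
})

test_that("gamma discretisation uses unit-mean category means", {
  expect_equal(discretize_gamma(0.7, 1), 1)
  set.seed(2)
  for (a in c(0.2, 0.7, 1, 3, 10)) {
    r <- discretize_gamma(a, 4)
    expect_equal(mean(r), 1)
    expect_true(all(diff(r) > 0))
  }
  # numeric-integration oracle for the category means at alpha = 1
  a <- 1; k <- 4
  bounds <- qgamma(seq(0, 1, length.out = k + 1), a, a)
  oracle <- sapply(seq_len(k), function(i)
    integrate(function(x) x * dgamma(x, a, a), bounds[i], bounds[i + 1])$value * k)
  oracle <- oracle / mean(oracle)
  expect_equal(discretize_gamma(a, k), oracle, tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration for all composition modes", {
  set.seed(5)
  tree4 <- ape::read.tree(text = "((A:0.2,B:0.35):0.1,(C:0.15,D:0.4):0.2);")
  aln <- random_nuc_alignment(c("A", "B", "C", "D"), 20, gap_prob = 0.1,
                              seed = 9)
  aln$mat[2, 4] <- "R" # ambiguity in the data path
  model <- substitution_model(alpha = 0.7, ncat = 3)

  comp_cv1 <- composition_cv1(c(.3, .2, .2, .3))
  pis <- rbind(c(.4, .1, .1, .4), c(.1, .4, .4, .1))
  comp_ndch <- composition_ndch(pis, c(1, 2, 1, 2, 1, 2, 1))
  pm <- matrix(rgamma(7 * 4, 2), 7, 4); pm <- pm / rowSums(pm)
  comp_ndch2 <- composition_ndch2(pm)

  for (comp in list(comp_cv1, comp_ndch, comp_ndch2)) {
    got <- tree_log_likelihood(aln, tree4, model, comp, per_site = TRUE)
    want <- brute_loglik(aln, tree4, model, comp)
    expect_lt(abs(got$total - want), 1e-8)
    expect_equal(sum(got$per_site), got$total, tolerance = 1e-8)
  }
})

test_that("two-taxon JC likelihood matches the closed form", {
  n <- 40; x <- 11; t <- 0.6
  m <- rbind(A = rep("A", n), B = c(rep("C", x), rep("A", n - x)))
  aln <- alignment(m)
  tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
  model <- substitution_model(alpha = 1, ncat = 1)
  got <- tree_log_likelihood(aln, tree, model, composition_cv1(rep(.25, 4)))$total
  pii <- 0.25 + 0.75 * exp(-4 * t / 3)
  pij <- 0.25 - 0.25 * exp(-4 * t / 3)
  want <- n * log(0.25) + (n - x) * log(pii) + x * log(pij)
  expect_lt(abs(got - want), 1e-10)
})

test_that("likelihood invariances: rooting, duplication, ambiguous leaves", {
  set.seed(6)
  taxa <- c("A", "B", "C", "D", "E")
  aln <- random_nuc_alignment(taxa, 40, gap_prob = 0.1, seed = 10)
  model <- substitution_model(alpha = 1.2, ncat = 4)
  comp <- composition_cv1(c(.3, .2, .25, .25))
  tr <- random_topology(taxa, 0.2)

  l0 <- tree_log_likelihood(aln, tr, model, comp)$total
  # CV1 likelihood invariant to root placement (reversibility)
  for (og in c("A", "C")) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    zero <- tr2$edge.length <= 0 | is.na(tr2$edge.length)
    tr2$edge.length[zero] <- 0
    expect_equal(tree_log_likelihood(aln, tr2, model, comp)$total, l0,
                 tolerance = 1e-8)
  }

  # duplicated column adds exactly its per-site term
  ps <- tree_log_likelihood(aln, tr, model, comp, per_site = TRUE)$per_site
  aln2 <- aln
  aln2$mat <- cbind(aln$mat, aln$mat[, 7])
  aln2$gene_bounds$end <- ncol(aln2$mat)
  l2 <- tree_log_likelihood(aln2, tr, model, comp)$total
  expect_equal(l2, l0 + ps[7], tolerance = 1e-9)

  # fully ambiguous leaf equals pruning it from the tree
  aln3 <- aln
  aln3$mat["E", ] <- "?"
  lfull <- tree_log_likelihood(aln3, tr, model, comp)$total
  trdrop <- ape::drop.tip(tr, "E")
  ldrop <- tree_log_likelihood(aln3, trdrop, model, comp)$total
  expect_lt(abs(lfull - ldrop), 1e-8)
})

test_that("single-leaf site likelihood is log pi_j", {
  aln <- alignment(matrix("G", 1, 1, dimnames = list("A", NULL)))
  tree <- ape::read.tree(text = "(A:0.3);")
  pi <- c(.1, .2, .3, .4)
  l <- tree_log_likelihood(aln, tree, substitution_model(ncat = 1),
                           composition_cv1(pi))$total
  expect_equal(l, log(pi[3]), tolerance = 1e-12)
})

test_that("NDCH2 requires one composition per node", {
  aln <- random_nuc_alignment(c("A", "B", "C"), 10, seed = 3)
  tree <- ape::read.tree(text = "((A:.1,B:.1):.1,C:.1);")
  pm <- matrix(0.25, 3, 4) # too few rows (5 nodes needed)
  expect_error(
    tree_log_likelihood(aln, tree, substitution_model(),
                        composition_ndch2(pm)),
    "one composition per node")
})

test_that("composition-annotated newick round-trips", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.35):0.1,(C:0.15,D:0.4):0.2);")
  set.seed(12)
  pm <- matrix(rgamma(7 * 4, 2), 7, 4); pm <- pm / rowSums(pm)
  comp <- composition_ndch2(pm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_tree(tree, comp, f)
  back <- read_annotated_tree(f)
  taxa <- sort(tree$tip.label)
  expect_setequal(degenphy:::tree_splits(back$tree, taxa),
                  degenphy:::tree_splits(tree, taxa))
  # compositions re-attach per node: compare tip vectors by taxon name
  po <- ape::reorder.phylo(tree, "postorder")
  for (tx in taxa) {
    want <- pm[match(tx, po$tip.label), ]
    got <- back$comp$pimat[match(tx, back$tree$tip.label), ]
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("empirical amino-acid models load and a PAML file round-trips", {
  m <- empirical_aa_model("JTT")
  expect_equal(m$S, 20L)
  expect_equal(m$R, t(m$R))
  fr <- attr(m, "freq")
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  expect_gt(fr[["A"]], 0.05) # JTT alanine frequency approx 0.077

  # synthetic PAML-format file written from a random symmetric matrix
  set.seed(8)
  R <- matrix(0, 20, 20); R[lower.tri(R)] <- rgamma(190, 1); R <- R + t(R)
  freq <- rgamma(20, 5); freq <- freq / sum(freq)
  f <- withr::local_tempfile(fileext = ".dat")
  lines <- sapply(2:20, function(i)
    paste(formatC(R[i, 1:(i - 1)], digits = 6, format = "f"), collapse = " "))
  writeLines(c(lines, paste(formatC(freq, digits = 6, format = "f"),
                            collapse = " ")), f)
  got <- read_paml_matrix(f)
  ord <- match(degenphy:::AA_CORE, degenphy:::PAML_AA_ORDER)
  expect_equal(got$R, R[ord, ord], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(as.numeric(got$freq), as.numeric(freq[ord]), tolerance = 1e-5)
})
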
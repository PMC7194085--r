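# Independent oracles and fixture builders shared across the suite.

# exhaustive-enumeration log-likelihood: sums over all internal-node state
# assignments, independent of the pruning code path
brute_loglik <- function(aln, tree, model, comp) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  S <- model$S
  pis <- t(degenphy:::node_compositions(comp, n_node, S))
  rates <- discretize_gamma(model$alpha, model$ncat)
  ptab <- degenphy:::partial_table(aln$alphabet)
  m <- aln$mat[tree$tip.label, , drop = FALSE]
  Pe <- lapply(rates, function(rate) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      chi <- tree$edge[e, 2]
      transition_probabilities(build_rate_matrix(model$R, pis[, chi]),
                               tree$edge.length[e], rate, pi = pis[, chi])
    })
  })
  internal <- (n_tip + 1):n_node
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  total <- 0
  for (site in seq_len(ncol(m))) {
    sl <- 0
    for (ri in seq_along(rates)) {
      tot <- 0
      for (gi in seq_len(nrow(grid))) {
        asg <- integer(n_node)
        asg[internal] <- grid[gi, ]
        pr <- pis[asg[n_tip + 1], n_tip + 1]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
          pr <- pr * if (chi <= n_tip)
            sum(Pe[[ri]][[e]][asg[par], ] * ptab[, m[chi, site]])
          else Pe[[ri]][[e]][asg[par], asg[chi]]
        }
        tot <- tot + pr
      }
      sl <- sl + tot / length(rates)
    }
    total <- total + log(sl)
  }
  total
}

random_nuc_alignment <- function(taxa, n_cols, gap_prob = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  syms <- c("A", "C", "G", "T", "-", "?")
  pr <- c(rep((1 - gap_prob) / 4, 4), gap_prob / 2, gap_prob / 2)
  m <- matrix(sample(syms, length(taxa) * n_cols, TRUE, pr),
              length(taxa), n_cols, dimnames = list(taxa, NULL))
  alignment(m)
}

# conjugate toy: multinomial likelihood, Dirichlet prior, exact posterior
# draws packaged as a dp_trace (branch lengths drawn from their prior and
# ignored by the likelihood, so the analytic marginal is untouched)
make_toy_trace <- function(counts, a_prior, n_draws, seed, bl_rate = 10) {
  set.seed(seed)
  S <- length(counts)
  apost <- a_prior + counts
  lmult <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  tree0 <- ape::read.tree(text = "(A:0.1,B:0.1);")
  samples <- vector("list", n_draws)
  ll <- lp <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    g <- rgamma(S, apost); pi <- g / sum(g)
    bl <- rexp(2, bl_rate)
    tr <- tree0; tr$edge.length <- bl
    ll[i] <- lmult + sum(counts * log(pi))
    lp[i] <- sum(dexp(bl, bl_rate, log = TRUE)) +
      degenphy:::ddirichlet_log(pi, a_prior)
    samples[[i]] <- list(tree = tr, alpha = 1, exch = NULL,
                         comps = rbind(pi), assignment = NULL, c = NULL,
                         splits = character(0))
  }
  spec <- model_spec(substitution_model(name = "fixed"), mode = "CV1")
  structure(list(samples = samples, log_lik = ll, log_prior = lp,
                 taxa = c("A", "B"), spec = spec, prior = prior_config(),
                 n_iterations = n_draws, sample_interval = 1, seed = seed),
            class = "dp_trace")
}

toy_log_marginal <- function(counts, a) {
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) +
    lgamma(sum(a)) - sum(lgamma(a)) +
    sum(lgamma(a + counts)) - lgamma(sum(a) + sum(counts))
}

# batch-means Monte-Carlo standard error (autocorrelation-aware)
batch_se <- function(x, n_batch = 20) {
  bm <- tapply(x, cut(seq_along(x), n_batch), mean)
  sd(bm) / sqrt(n_batch)
}

# fabricate a minimal trace whose samples carry given split sets
fake_split_trace <- function(split_sets, taxa) {
  samples <- lapply(split_sets, function(sp)
    list(tree = NULL, alpha = 1, exch = NULL, comps = rbind(rep(0.25, 4)),
         assignment = NULL, c = NULL, splits = sp))
  structure(list(samples = samples, log_lik = numeric(length(samples)),
                 log_prior = numeric(length(samples)), taxa = taxa,
                 spec = model_spec(substitution_model(), "CV1"),
                 prior = prior_config(), n_iterations = length(samples),
                 sample_interval = 1, seed = 1), class = "dp_trace")
}
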
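# Metropolis-Hastings over topology, branch lengths, gamma shape,
# exchangeabilities and composition vectors (CV1 / NDCH-k / NDCH2), with
# split-frequency diagnostics and majority-rule consensus.

#' Prior configuration for the MCMC
#'
#' Branch lengths are iid exponential; topology uniform over labelled
#' topologies; exchangeabilities and CV1/NDCH composition vectors flat
#' Dirichlet; the gamma shape uniform on `(0, alpha_max]`.  Under NDCH2
#' each node's vector is Dirichlet(`c * pihat`) around the empirical
#' composition `pihat`, with concentration `c` itself sampled under an
#' exponential hyperprior (mean `c_mean`), weakly favouring
#' near-homogeneity and letting the data pull node vectors apart.
#'
#' @param bl_mean mean of the exponential branch-length prior.
#' @param alpha_max upper bound of the uniform gamma-shape prior.
#' @param c_mean mean of the exponential hyperprior on the NDCH2
#'   concentration.
#' @return object of class `dp_prior`.
#' @export
prior_config <- function(bl_mean = 0.1, alpha_max = 20, c_mean = 100) {
  stopifnot(bl_mean > 0, alpha_max > 0, c_mean > 0)
  structure(list(bl_mean = bl_mean, alpha_max = alpha_max, c_mean = c_mean),
            class = "dp_prior")
}

#' Model specification for an MCMC analysis
#'
#' @param model a `dp_submodel` template; for `"GTR"` nucleotide models the
#'   exchangeabilities are sampled, for empirical amino-acid models they
#'   stay fixed.
#' @param mode composition mode: `"CV1"`, `"NDCH"` or `"NDCH2"`.
#' @param k number of composition vectors for NDCH.
#' @return object of class `dp_modelspec`.
#' @export
model_spec <- function(model, mode = c("CV1", "NDCH", "NDCH2"), k = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "dp_submodel"), k >= 1)
  structure(list(model = model, mode = mode, k = as.integer(k),
                 estimate_exch = model$name == "GTR"),
            class = "dp_modelspec")
}

#' Empirical composition of an alignment
#'
#' State frequencies pooled over all taxa, counting unambiguous core
#' symbols only, with a 0.5 pseudocount per state.
#'
#' @param aln a `dp_alignment`.
#' @return simplex vector over the alphabet's core states.
#' @export
empirical_composition <- function(aln) {
  core <- if (aln$alphabet == "amino_acid") AA_CORE else NUC_CORE
  cnt <- table(factor(aln$mat, levels = core))
  as.numeric(cnt + 0.5) / sum(cnt + 0.5)
}

#' NDCH2 log-prior on node compositions
#'
#' Sum over nodes of `log Dirichlet(pi_v | c * pihat)`.
#'
#' @param compositions matrix of node composition vectors (rows) or a
#'   single vector.
#' @param empirical_comp empirical composition `pihat` (simplex).
#' @param c concentration (> 0).
#' @return log prior density; `-Inf` (with a warning) if any entry is zero.
#' @export
ndch2_log_prior <- function(compositions, empirical_comp, c) {
  stopifnot(c > 0)
  if (is.null(dim(compositions))) compositions <- rbind(compositions)
  if (any(compositions <= 0)) {
    warning("composition entry at the simplex boundary; log-prior is -Inf")
    return(-Inf)
  }
  a <- c * empirical_comp / sum(empirical_comp)
  sum(apply(compositions, 1, ddirichlet_log, a = a))
}

ddirichlet_log <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

log_double_factorial <- function(n) {
  if (n <= 1) return(0)
  sum(log(seq(n, 2, by = -2)))
}

# full (normalised) log prior of a chain state
state_log_prior <- function(st, prior, spec, emp) {
  n_tip <- length(st$tree$tip.label)
  lp <- sum(dexp(st$tree$edge.length, rate = 1 / prior$bl_mean, log = TRUE))
  lp <- lp - log_double_factorial(2L * n_tip - 5L) # uniform topology
  if (st$alpha <= 0 || st$alpha > prior$alpha_max) return(-Inf)
  lp <- lp - log(prior$alpha_max)
  if (spec$estimate_exch) {
    m <- length(st$exch)
    lp <- lp + lgamma(m) # flat Dirichlet
  }
  if (spec$mode == "NDCH2") {
    lp <- lp + suppressWarnings(ndch2_log_prior(st$comps, emp, st$c)) +
      dexp(st$c, rate = 1 / prior$c_mean, log = TRUE)
  } else {
    S <- ncol(st$comps)
    lp <- lp + nrow(st$comps) * lgamma(S) # flat Dirichlet per vector
    if (spec$mode == "NDCH") lp <- lp - 0 # uniform node assignment
  }
  lp
}

exch_to_R <- function(exch, S) {
  R <- matrix(0, S, S)
  R[upper.tri(R)] <- exch
  R + t(R)
}

state_model <- function(st, spec) {
  R <- if (spec$estimate_exch) exch_to_R(st$exch, spec$model$S) else spec$model$R
  list(R = R, alpha = st$alpha, ncat = spec$model$ncat, S = spec$model$S)
}

state_comp <- function(st, spec) {
  switch(spec$mode,
    CV1 = composition_cv1(st$comps[1, ]),
    NDCH = composition_ndch(st$comps, st$assignment),
    NDCH2 = composition_ndch2(st$comps))
}

# centred Dirichlet proposal with boundary floor; returns NULL if the
# proposal leaves the admissible region (caller rejects)
propose_dirichlet <- function(x, conc, floor = 1e-6) {
  a <- conc * x
  g <- rgamma(length(x), shape = a, rate = 1)
  if (any(g == 0)) return(NULL)
  xp <- g / sum(g)
  if (any(xp < floor)) return(NULL)
  lfwd <- ddirichlet_log(xp, a)
  lrev <- ddirichlet_log(x, conc * xp)
  list(x = xp, lhr = lrev - lfwd)
}

#' Run one MCMC chain
#'
#' Single-site Metropolis-Hastings: each iteration picks one move (NNI on
#' an internal edge, branch-length multiplier, gamma-shape walk on the log
#' scale, centred Dirichlet updates of exchangeabilities and composition
#' vectors, NDCH node reassignment, NDCH2 concentration walk) and accepts
#' by the usual ratio.  Deterministic given `seed`.
#'
#' @param aln a `dp_alignment` (all its taxa are used).
#' @param spec a `dp_modelspec`.
#' @param prior a `dp_prior`.
#' @param n_iterations total iterations (>= 1).
#' @param sample_interval record every this many iterations.
#' @param seed RNG seed.
#' @param init_tree optional starting tree (default random from the prior).
#' @param fix_topology disable topology moves.
#' @param topology_warmup_fraction fraction of iterations at the start of
#'   the run during which topology moves are suppressed, letting branch
#'   lengths and compositions adapt to the starting topology before any
#'   rearrangement is judged (0 disables; used by basin-coverage replicate
#'   designs).
#' @param likelihood_off sample from the prior only (diagnostics).
#' @param tuning named list overriding proposal tuning constants
#'   (`bl_lambda`, `alpha_window`, `c_window`, `conc_comp`, `conc_exch`).
#' @return object of class `dp_trace`.
#' @export
run_chain <- function(aln, spec, prior = prior_config(), n_iterations = 10000L,
                      sample_interval = 10L, seed = 1L, init_tree = NULL,
                      fix_topology = FALSE, topology_warmup_fraction = 0,
                      likelihood_off = FALSE, tuning = list()) {
  stopifnot(inherits(aln, "dp_alignment"), inherits(spec, "dp_modelspec"),
            n_iterations >= 1)
  set.seed(seed)
  tun <- modifyList(list(bl_lambda = 1.0, alpha_window = 0.5, c_window = 1.0,
                         conc_comp = 600, conc_exch = 800), tuning)
  taxa <- aln_taxa(aln)
  taxa_ref <- sort(taxa)
  ld <- if (likelihood_off) NULL else make_lik_data(aln, taxa)
  emp <- empirical_composition(aln)
  S <- spec$model$S
  n_tip <- length(taxa)
  n_node <- 2L * n_tip - 1L

  init_tree <- if (is.null(init_tree)) random_topology(taxa, prior$bl_mean)
               else ape::reorder.phylo(init_tree, "postorder")
  st <- list(
    tree = init_tree,
    alpha = spec$model$alpha,
    exch = {
      m <- S * (S - 1) / 2
      spec$model$R[upper.tri(spec$model$R)] / sum(spec$model$R[upper.tri(spec$model$R)])
    },
    comps = switch(spec$mode,
      CV1 = rbind(emp),
      NDCH = matrix(emp, spec$k, S, byrow = TRUE) *
        matrix(runif(spec$k * S, 0.95, 1.05), spec$k, S),
      NDCH2 = {
        # data-informed start: every tip node at its own empirical
        # composition, internal nodes at the global one, so early topology
        # moves are judged with per-lineage composition already in place
        m <- matrix(emp, n_node, S, byrow = TRUE)
        core <- if (spec$model$states == "amino_acid") AA_CORE else NUC_CORE
        for (i in seq_len(n_tip)) {
          cnt <- table(factor(aln$mat[init_tree$tip.label[i], ],
                              levels = core))
          m[i, ] <- as.numeric(cnt + 1) / sum(cnt + 1)
        }
        m
      }),
    assignment = if (spec$mode == "NDCH")
      sample.int(spec$k, n_node, replace = TRUE) else NULL,
    c = prior$c_mean)
  st$comps <- st$comps / rowSums(st$comps)

  loglik <- function(s) {
    if (likelihood_off) return(0)
    lik_eval(ld, s$tree, state_model(s, spec), state_comp(s, spec))$total
  }
  ll <- loglik(st)
  lp <- state_log_prior(st, prior, spec, emp)
  if (!is.finite(ll) || !is.finite(lp))
    stop(sprintf("non-finite posterior at initialization (logL=%g, logPrior=%g)",
                 ll, lp))

  moves <- c(nni = if (!fix_topology && n_tip >= 3) 3 else 0,
             jolt = if (!fix_topology && n_tip >= 3) 1.5 else 0,
             bl = 3, alpha = 1,
             exch = if (spec$estimate_exch) 1.5 else 0,
             comp = switch(spec$mode, CV1 = 2, NDCH = 3, NDCH2 = 4),
             # conditional-prior redraw of one node's vector: breaks the
             # c-composition funnel that defeats the centred walk alone
             compprior = if (spec$mode == "NDCH2") 0.7 else 0,
             assign = if (spec$mode == "NDCH") 1.5 else 0,
             cmove = if (spec$mode == "NDCH2") 1 else 0)
  moves <- moves[moves > 0]
  mprob <- moves / sum(moves)
  prop_n <- acc_n <- setNames(integer(length(moves)), names(moves))

  n_samp <- n_iterations %/% sample_interval
  samples <- vector("list", n_samp)
  log_lik <- log_prior <- numeric(n_samp)
  si <- 0L

  warm_end <- floor(topology_warmup_fraction * n_iterations)
  for (it in seq_len(n_iterations)) {
    mv <- sample(names(moves), 1L, prob = mprob)
    if (it <= warm_end && mv %in% c("nni", "jolt")) next
    prop_n[mv] <- prop_n[mv] + 1L
    cand <- st
    lhr <- 0
    lik_changed <- TRUE
    ok <- TRUE
    if (mv == "nni") {
      cand$tree <- nni_propose(st$tree)
    } else if (mv == "jolt") {
      # NNI coupled with a fresh draw of the rearranged internal branch
      # from its exponential prior and, under NDCH2, of the two incident
      # node compositions from their Dirichlet prior; those proposal
      # densities cancel against the prior, so the move can cross the deep
      # valleys that separate topology basins when data are informative
      nn <- nni_propose_full(st$tree)
      if (is.na(nn$edge)) ok <- FALSE else {
        cand$tree <- nn$tree
        t_old <- cand$tree$edge.length[nn$edge]
        t_new <- rexp(1, rate = 1 / prior$bl_mean)
        cand$tree$edge.length[nn$edge] <- t_new
        lhr <- dexp(t_old, 1 / prior$bl_mean, log = TRUE) -
          dexp(t_new, 1 / prior$bl_mean, log = TRUE)
        if (spec$mode == "NDCH2") {
          a_pr <- st$c * emp
          for (v in c(nn$u, nn$v)) {
            pr <- rgamma(S, shape = a_pr, rate = 1)
            pr <- pr / sum(pr)
            if (any(pr < 1e-6)) { ok <- FALSE; break }
            lhr <- lhr + ddirichlet_log(st$comps[v, ], a_pr) -
              ddirichlet_log(pr, a_pr)
            cand$comps[v, ] <- pr
          }
        }
      }
    } else if (mv == "bl") {
      e <- sample.int(nrow(st$tree$edge), 1L)
      f <- exp(tun$bl_lambda * (runif(1) - 0.5))
      cand$tree$edge.length[e] <- st$tree$edge.length[e] * f
      lhr <- log(f)
    } else if (mv == "alpha") {
      f <- exp(tun$alpha_window * (runif(1) - 0.5))
      cand$alpha <- st$alpha * f
      lhr <- log(f)
    } else if (mv == "exch") {
      pr <- propose_dirichlet(st$exch, tun$conc_exch)
      if (is.null(pr)) ok <- FALSE else { cand$exch <- pr$x; lhr <- pr$lhr }
    } else if (mv == "comp") {
      r <- sample.int(nrow(st$comps), 1L)
      pr <- propose_dirichlet(st$comps[r, ], tun$conc_comp)
      if (is.null(pr)) ok <- FALSE else { cand$comps[r, ] <- pr$x; lhr <- pr$lhr }
    } else if (mv == "compprior") {
      r <- sample.int(nrow(st$comps), 1L)
      a_pr <- st$c * emp
      g <- rgamma(S, shape = a_pr, rate = 1)
      pr <- g / sum(g)
      if (any(pr < 1e-6)) ok <- FALSE else {
        cand$comps[r, ] <- pr
        lhr <- ddirichlet_log(st$comps[r, ], a_pr) - ddirichlet_log(pr, a_pr)
      }
    } else if (mv == "assign") {
      v <- sample.int(n_node, 1L)
      cand$assignment[v] <- sample.int(spec$k, 1L)
    } else if (mv == "cmove") {
      f <- exp(tun$c_window * (runif(1) - 0.5))
      cand$c <- st$c * f
      lhr <- log(f)
      lik_changed <- FALSE
    }
    if (ok) {
      lp2 <- state_log_prior(cand, prior, spec, emp)
      if (is.finite(lp2)) {
        ll2 <- if (lik_changed) loglik(cand) else ll
        if (log(runif(1)) < (ll2 + lp2) - (ll + lp) + lhr) {
          st <- cand; ll <- ll2; lp <- lp2
          acc_n[mv] <- acc_n[mv] + 1L
        }
      }
    }
    if (it %% sample_interval == 0L) {
      si <- si + 1L
      samples[[si]] <- list(tree = st$tree, alpha = st$alpha, exch = st$exch,
                            comps = st$comps, assignment = st$assignment,
                            c = st$c,
                            splits = tree_splits(st$tree, taxa_ref))
      log_lik[si] <- ll
      log_prior[si] <- lp
    }
  }
  structure(list(samples = samples[seq_len(si)],
                 log_lik = log_lik[seq_len(si)],
                 log_prior = log_prior[seq_len(si)],
                 taxa = taxa_ref, spec = spec, prior = prior,
                 empirical_comp = emp,
                 n_iterations = n_iterations,
                 sample_interval = sample_interval, seed = seed,
                 acceptance = data.frame(move = names(moves),
                                         proposed = as.integer(prop_n),
                                         accepted = as.integer(acc_n),
                                         rate = ifelse(prop_n > 0,
                                                       acc_n / pmax(prop_n, 1L),
                                                       NA))),
            class = "dp_trace")
}

#' @export
print.dp_trace <- function(x, ...) {
  cat(sprintf("<dp_trace> %d samples (%d iterations, interval %d), %s/%s\n",
              length(x$samples), x$n_iterations, x$sample_interval,
              x$spec$model$name, x$spec$mode))
  invisible(x)
}

post_burnin_idx <- function(trace, burnin_fraction = 0.25) {
  n <- length(trace$samples)
  keep <- seq.int(floor(n * burnin_fraction) + 1L, n)
  if (!length(keep)) stop("no post-burn-in samples")
  keep
}

split_frequencies <- function(trace, burnin_fraction = 0.25) {
  idx <- post_burnin_idx(trace, burnin_fraction)
  all <- unlist(lapply(trace$samples[idx], `[[`, "splits"))
  tab <- table(all) / length(idx)
  setNames(as.numeric(tab), names(tab))
}

#' Average standard deviation of split frequencies between two runs
#'
#' Mean over qualifying splits (frequency >= `min_freq` in at least one
#' run) of the sample standard deviation of the two runs' frequencies.
#'
#' @param trace_a,trace_b `dp_trace` objects over identical taxon sets.
#' @param burnin_fraction fraction of samples discarded.
#' @param min_freq inclusion threshold (default 0.1).
#' @return non-negative number (0, with a warning, if no split qualifies).
#' @export
asdsf <- function(trace_a, trace_b, burnin_fraction = 0.25, min_freq = 0.1) {
  if (!identical(trace_a$taxa, trace_b$taxa))
    stop("traces are over different taxon sets")
  fa <- split_frequencies(trace_a, burnin_fraction)
  fb <- split_frequencies(trace_b, burnin_fraction)
  keys <- union(names(fa)[fa >= min_freq], names(fb)[fb >= min_freq])
  if (!length(keys)) {
    warning("no splits above min_freq; ASDSF defined as 0")
    return(0)
  }
  ga <- ifelse(keys %in% names(fa), fa[keys], 0)
  gb <- ifelse(keys %in% names(fb), fb[keys], 0)
  mean(abs(ga - gb) / sqrt(2)) # two-point sample sd
}

#' Majority-rule consensus tree with posterior probabilities
#'
#' Pools post-burn-in samples of one or more traces and keeps exactly the
#' splits with pooled frequency strictly greater than `cutoff` (ties at
#' the cutoff are excluded), annotating each retained split with its
#' frequency as a node label.
#'
#' @param traces a `dp_trace` or list of them (same taxa).
#' @param burnin_fraction fraction discarded per trace.
#' @param cutoff frequency cutoff (default 0.5).
#' @return `dp_consensus` list: `tree` (ape::phylo, node labels = PP),
#'   `splits` data.frame of all observed splits with pooled frequencies.
#' @export
majority_rule_consensus <- function(traces, burnin_fraction = 0.25,
                                    cutoff = 0.5) {
  if (inherits(traces, "dp_trace")) traces <- list(traces)
  taxa <- traces[[1]]$taxa
  counts <- list(); n_tot <- 0L
  all <- unlist(lapply(traces, function(tr) {
    idx <- post_burnin_idx(tr, burnin_fraction)
    n_tot <<- n_tot + length(idx)
    unlist(lapply(tr$samples[idx], `[[`, "splits"))
  }))
  tab <- table(all) / n_tot
  freq <- setNames(as.numeric(tab), names(tab))
  keep <- freq > cutoff
  clades <- lapply(names(freq)[keep], function(k)
    taxa[strsplit(k, "")[[1]] == "1"])
  tree <- build_tree_from_clades(clades, freq[keep], taxa)
  structure(list(tree = tree,
                 splits = data.frame(split = names(freq),
                                     frequency = unname(freq)),
                 taxa = taxa, cutoff = cutoff, n_samples = n_tot),
            class = "dp_consensus")
}

#' @export
print.dp_consensus <- function(x, ...) {
  cat(sprintf("<dp_consensus> %d taxa, %d splits > %.2f from %d samples\n",
              length(x$taxa), sum(x$splits$frequency > x$cutoff), x$cutoff,
              x$n_samples))
  invisible(x)
}

#' Posterior probability of a named split
#'
#' @param traces a `dp_trace` or list of them.
#' @param clade character vector of taxa on one side of the split.
#' @param burnin_fraction fraction discarded.
#' @return pooled frequency in `[0, 1]`.
#' @export
split_support <- function(traces, clade, burnin_fraction = 0.25) {
  if (inherits(traces, "dp_trace")) traces <- list(traces)
  taxa <- traces[[1]]$taxa
  key <- split_key(clade, taxa)
  hits <- 0L; tot <- 0L
  for (tr in traces) {
    idx <- post_burnin_idx(tr, burnin_fraction)
    tot <- tot + length(idx)
    hits <- hits + sum(vapply(tr$samples[idx],
                              function(s) key %in% s$splits, TRUE))
  }
  hits / tot
}

#' Convergence report for a pair of runs
#'
#' @param trace_a,trace_b `dp_trace` objects.
#' @param burnin_fraction fraction discarded.
#' @param min_freq ASDSF split-inclusion threshold.
#' @param seed seed for the marginal-likelihood bootstrap.
#' @return `dp_convergence` list with `asdsf`, per-run marginal likelihoods,
#'   `marglik_diff` and acceptance-rate tables.
#' @export
convergence_report <- function(trace_a, trace_b, burnin_fraction = 0.25,
                               min_freq = 0.1, seed = 1L) {
  ml_a <- estimate_marginal_likelihood(trace_a, burnin_fraction = burnin_fraction,
                                       seed = seed)
  ml_b <- estimate_marginal_likelihood(trace_b, burnin_fraction = burnin_fraction,
                                       seed = seed + 1L)
  structure(list(asdsf = asdsf(trace_a, trace_b, burnin_fraction, min_freq),
                 marglik = c(ml_a$log_marginal, ml_b$log_marginal),
                 marglik_diff = abs(ml_a$log_marginal - ml_b$log_marginal),
                 acceptance = list(trace_a$acceptance, trace_b$acceptance)),
            class = "dp_convergence")
}

#' Convergence decision rule
#'
#' Chains are considered converged when the ASDSF is below `asdsf_max` and
#' the between-run marginal-likelihood difference is below
#' `marglik_max_diff` (natural-log units).
#'
#' @param report a `dp_convergence` (or any list with `asdsf` and
#'   `marglik_diff`).
#' @param asdsf_max ASDSF threshold (default 0.01).
#' @param marglik_max_diff marginal-likelihood threshold (default 10).
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
check_convergence <- function(report, asdsf_max = 0.01,
                              marglik_max_diff = 10.0) {
  reasons <- character(0)
  if (!(report$asdsf < asdsf_max))
    reasons <- c(reasons, sprintf("ASDSF %.4f >= %.4f", report$asdsf, asdsf_max))
  if (!(report$marglik_diff < marglik_max_diff))
    reasons <- c(reasons, sprintf("marginal likelihood difference %.2f >= %.2f",
                                  report$marglik_diff, marglik_max_diff))
  list(pass = length(reasons) == 0L, reasons = reasons)
}
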
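# X^2 composition-homogeneity statistic and posterior-predictive test.

#' X-squared statistic of composition homogeneity
#'
#' `X2 = sum_t sum_s (O_ts - E_ts)^2 / E_ts` over taxa t and states s, with
#' `E_ts` = (taxon t's counted sites) x (global state frequency).  Gaps,
#' missing and ambiguity symbols are excluded from the counts; states with
#' zero global frequency are dropped from the sum with a warning.
#'
#' @param aln a `dp_alignment` with >= 2 taxa.
#' @return the statistic (0 when every taxon matches the global composition).
#' @export
x2_statistic <- function(aln) {
  stopifnot(nrow(aln$mat) >= 2)
  core <- if (aln$alphabet == "amino_acid") AA_CORE else NUC_CORE
  O <- t(apply(aln$mat, 1, function(r) table(factor(r, levels = core))))
  tot <- colSums(O)
  if (any(tot == 0)) {
    warning("state(s) with zero global frequency dropped: ",
            paste(core[tot == 0], collapse = ", "))
    O <- O[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  gf <- tot / sum(tot)
  n_t <- rowSums(O)
  E <- n_t %o% gf
  sum((O - E)^2 / E)
}

#' Posterior-predictive p-value for composition homogeneity
#'
#' For each of `n_draws` evenly spaced post-burn-in posterior samples, a
#' replicate alignment of identical dimensions is simulated under the
#' drawn tree and parameters, the observed gap/missing mask is re-applied
#' so counts are like-for-like, and X^2 is computed.  The tail-area
#' probability is the fraction of simulated statistics greater than or
#' equal to the observed one (ties count toward the tail); values >= 0.05
#' are conventionally read as acceptance of the composition model.
#'
#' @param trace a `dp_trace` from [run_chain()] on `aln`.
#' @param aln the observed `dp_alignment`.
#' @param n_draws number of posterior draws to use.
#' @param seed RNG seed for the replicate simulations.
#' @param burnin_fraction fraction of samples discarded.
#' @return object of class `dp_x2result` with fields `observed`,
#'   `simulated`, `p_value`, `n_draws`, `seed`, `fits` (p >= 0.05).
#' @export
posterior_predictive_pvalue <- function(trace, aln, n_draws = 100L, seed = 1L,
                                        burnin_fraction = 0.25) {
  idx <- post_burnin_idx(trace, burnin_fraction)
  if (n_draws > length(idx))
    stop(sprintf("n_draws (%d) exceeds post-burn-in samples (%d)",
                 n_draws, length(idx)))
  set.seed(seed)
  use <- idx[unique(round(seq(1, length(idx), length.out = n_draws)))]
  obs <- x2_statistic(aln)
  mask <- !is_state(aln$mat, aln) # TRUE where gap/missing
  spec <- trace$spec
  sims <- vapply(use, function(i) {
    s <- trace$samples[[i]]
    comp <- state_comp(s, spec)
    model <- state_model(s, spec)
    rep_aln <- simulate_replicate(s$tree, model, comp, aln_ncol(aln),
                                  aln$alphabet)
    m <- rep_aln$mat[rownames(aln$mat), , drop = FALSE]
    m[mask] <- MISSING
    rep_aln$mat <- m
    x2_statistic(rep_aln)
  }, 0)
  p <- mean(sims >= obs)
  structure(list(observed = obs, simulated = sims, p_value = p,
                 n_draws = length(use), seed = seed, fits = p >= 0.05),
            class = "dp_x2result")
}

# one replicate under explicit tree/model/composition (ppred work-horse)
simulate_replicate <- function(tree, model, comp, n_sites, alphabet) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- length(tree$tip.label) + tree$Nnode
  S <- model$S
  pis <- t(node_compositions(comp, n_node, S))
  Qs <- array(0, c(S, S, n_node))
  for (v in seq_len(n_node)) Qs[, , v] <- build_rate_matrix(model$R, pis[, v])
  rates <- discretize_gamma(model$alpha, model$ncat)
  rs <- rates[sample.int(length(rates), n_sites, replace = TRUE)]
  st <- sim_states(tree, Qs, pis, pis[, length(tree$tip.label) + 1L], rs,
                   tree$tip.label)
  symbols <- if (S == 4L) NUC_CORE else AA_CORE
  mat <- matrix(symbols[st], nrow(st), n_sites,
                dimnames = list(tree$tip.label, NULL))
  alignment(mat, alphabet = if (S == 4L) "nucleotide" else "amino_acid")
}

#' @export
#' @importFrom graphics abline hist
plot.dp_x2result <- function(x, ...) {
  hist(x$simulated, breaks = 20, main = "posterior-predictive X2",
       xlab = "simulated X2",
       xlim = range(c(x$simulated, x$observed)), ...)
  abline(v = x$observed, lwd = 2)
  invisible(x)
}

#' @export
print.dp_x2result <- function(x, ...) {
  cat(sprintf("<dp_x2result> observed X2 = %.3f, p = %.4f (%d draws) -> %s\n",
              x$observed, x$p_value, x$n_draws,
              if (x$fits) "model fits" else "model rejected"))
  invisible(x)
}
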
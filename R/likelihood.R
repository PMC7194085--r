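# Tree log-likelihood: pattern compression, ambiguity-aware tip partials,
# per-node rate matrices, call into the C++ pruning kernel.

# partial-likelihood lookup row per symbol for an alphabet
partial_table <- function(alphabet) {
  if (alphabet %in% c("nucleotide", "degenerate_nucleotide")) {
    syms <- c(NUC_CORE, NUC_AMBIG, GAP, MISSING)
    tab <- matrix(0, 4, length(syms), dimnames = list(NUC_CORE, syms))
    for (s in c(NUC_CORE, NUC_AMBIG))
      tab[strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]], s] <- 1
    tab[, c(GAP, MISSING)] <- 1
  } else {
    syms <- c(AA_CORE, "X", GAP, MISSING)
    tab <- matrix(0, 20, length(syms), dimnames = list(AA_CORE, syms))
    for (s in AA_CORE) tab[s, s] <- 1
    tab[, c("X", GAP, MISSING)] <- 1
  }
  tab
}

# compress columns into unique site patterns (restricted to `taxa`)
compress_patterns <- function(aln, taxa) {
  m <- aln$mat[taxa, , drop = FALSE]
  keys <- do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  u <- !duplicated(keys)
  idx <- match(keys, keys[u])
  list(mat = m[, u, drop = FALSE], weights = as.numeric(table(idx)),
       index = idx)
}

# precomputed, state-independent part of a likelihood evaluation; reused
# across MCMC iterations
make_lik_data <- function(aln, taxa) {
  stopifnot(all(taxa %in% aln_taxa(aln)))
  pat <- compress_patterns(aln, taxa)
  ptab <- partial_table(aln$alphabet)
  S <- nrow(ptab)
  npat <- ncol(pat$mat)
  cube <- array(0, c(S, npat, length(taxa)))
  for (i in seq_along(taxa)) cube[, , i] <- ptab[, pat$mat[i, ]]
  list(taxa = taxa, S = S, cube = cube, weights = pat$weights,
       index = pat$index, npat = npat)
}

# core evaluation against precomputed data; tree tips must equal data taxa
lik_eval <- function(ld, tree, model, comp, per_site = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ord <- match(tree$tip.label, ld$taxa)
  if (anyNA(ord)) stop("tree tips not in alignment: ",
                       paste(setdiff(tree$tip.label, ld$taxa), collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  pis <- t(node_compositions(comp, n_node, ld$S)) # S x n_node
  Qs <- array(0, c(ld$S, ld$S, n_node))
  for (v in seq_len(n_node)) Qs[, , v] <- build_rate_matrix(model$R, pis[, v])
  rates <- discretize_gamma(model$alpha, model$ncat)
  ll <- cpp_pruning(t(tree$edge), tree$edge.length, n_tip, n_node, root,
                    ld$cube[, , ord, drop = FALSE], Qs, pis, pis[, root],
                    rates)
  total <- sum(ll * ld$weights)
  out <- list(total = total,
              per_site = if (per_site) ll[ld$index] else NULL)
  class(out) <- "dp_sitelik"
  out
}

#' Phylogenetic log-likelihood with per-node composition vectors
#'
#' Felsenstein pruning over unique site patterns.  The branch leading into
#' node v uses a rate matrix built from v's composition vector (each branch
#' rescaled to one expected substitution per unit length under its own
#' composition); the root's vector weights the root partials.  Gap, missing
#' and IUPAC-ambiguity symbols contribute leaf partials of one over their
#' expansion set, which is how codon-degenerate data enter the likelihood.
#' Rate variation is a discrete-gamma mixture with equal category weights.
#'
#' @param aln a `dp_alignment`.
#' @param tree rooted binary `ape::phylo`; tip labels must be alignment taxa.
#' @param model a `dp_submodel`.
#' @param comp a `dp_composition` ([composition_cv1()], [composition_ndch()],
#'   [composition_ndch2()]).
#' @param per_site also return the per-site log-likelihood vector.
#' @return `dp_sitelik` list with `total` and optionally `per_site`.
#' @export
tree_log_likelihood <- function(aln, tree, model, comp, per_site = FALSE) {
  ld <- make_lik_data(aln, tree$tip.label)
  lik_eval(ld, tree, model, comp, per_site = per_site)
}

#' @export
print.dp_sitelik <- function(x, ...) {
  cat(sprintf("<dp_sitelik> total log-likelihood %.6f\n", x$total))
  invisible(x)
}
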
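# Synthetic data: sequences evolved on known trees with lineage-specific
# compositions, optional codon mode with accelerated synonymous change
# (third-position saturation), and per-gene taxon dropout.

#' Describe a simulation scenario
#'
#' @param tree rooted binary `ape::phylo` with branch lengths.
#' @param comp a `dp_composition` (the composition regime; for codon mode
#'   this is the nucleotide composition driving the codon chain).
#' @param model a `dp_submodel` (nucleotide or amino acid; in codon mode the
#'   nucleotide model whose synonymous changes are accelerated).
#' @param mode `"nucleotide"`, `"amino_acid"` or `"codon"`.
#' @param gene_lengths integer vector of per-gene lengths in columns
#'   (divisible by 3 in codon mode).
#' @param dropout per-gene per-taxon probability that a gene sequence is
#'   missing entirely (in `[0, 1)`).
#' @param omega_syn synonymous rate multiplier (>= 1), codon mode only.
#' @param genetic_code NCBI table for codon mode.
#' @param seed RNG seed for [simulate_alignment()].
#' @return object of class `dp_scenario`.
#' @export
simulation_scenario <- function(tree, comp, model, mode = "nucleotide",
                                gene_lengths = 1000L, dropout = 0,
                                omega_syn = 1, genetic_code = 1, seed = 1L) {
  stopifnot(inherits(comp, "dp_composition"), inherits(model, "dp_submodel"),
            mode %in% c("nucleotide", "amino_acid", "codon"),
            dropout >= 0, dropout < 1, omega_syn >= 1)
  if (mode == "codon" && any(gene_lengths %% 3L != 0L))
    stop("codon-mode gene lengths must be divisible by 3")
  structure(list(tree = tree, comp = comp, model = model, mode = mode,
                 gene_lengths = as.integer(gene_lengths), dropout = dropout,
                 omega_syn = omega_syn, genetic_code = genetic_code,
                 seed = seed),
            class = "dp_scenario")
}

# evolve states down the tree; returns taxa x sites integer state matrix
sim_states <- function(tree, Qs, pis, root_pi, rates_per_site, labels) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  S <- length(root_pi)
  n_sites <- length(rates_per_site)
  ucat <- sort(unique(rates_per_site))
  states <- matrix(0L, n_node, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(S, n_sites, replace = TRUE, prob = root_pi)
  for (e in rev(seq_len(nrow(tree$edge)))) { # preorder
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    for (r in ucat) {
      P <- transition_probabilities(Qs[, , chi], t, rate = r,
                                    pi = pis[, chi])
      idx <- which(rates_per_site == r)
      ps <- states[par, idx]
      for (s in unique(ps)) {
        here <- idx[ps == s]
        states[chi, here] <- sample.int(S, length(here), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# codon-state machinery: sense codons of a code, and the codon rate matrix
# with single-nucleotide moves, synonymous ones multiplied by omega_syn
sense_codons <- function(genetic_code = 1) {
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  names(code)[code != "*"]
}

codon_rate_matrix <- function(R_nuc, pi_nuc, omega_syn, genetic_code = 1) {
  code <- Biostrings::getGeneticCode(as.character(genetic_code))
  cods <- sense_codons(genetic_code)
  n <- length(cods)
  cm <- do.call(rbind, strsplit(cods, ""))
  Q <- matrix(0, n, n, dimnames = list(cods, cods))
  nuc <- NUC_CORE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffpos <- which(cm[i, ] != cm[j, ])
    if (length(diffpos) != 1L) next
    a <- match(cm[i, diffpos], nuc); b <- match(cm[j, diffpos], nuc)
    syn <- code[cods[i]] == code[cods[j]]
    Q[i, j] <- R_nuc[a, b] * pi_nuc[b] * if (syn) omega_syn else 1
  }
  diag(Q) <- -rowSums(Q)
  # root/state distribution: product measure over positions, renormalised
  p0 <- apply(cm, 1, function(x) prod(pi_nuc[match(x, nuc)]))
  p0 <- p0 / sum(p0)
  beta <- -sum(p0 * diag(Q))
  list(Q = Q / beta, p0 = p0, codons = cods)
}

#' Simulate a multi-gene alignment under a scenario
#'
#' Root states are drawn from the root node's composition; states evolve
#' edge by edge with the same branch-to-composition convention as the
#' likelihood engine (the branch into node v uses v's composition vector,
#' each rate matrix rescaled to mean rate one).  Per-site rates are drawn
#' from the discrete-gamma categories of the scenario's model.  In codon
#' mode whole codons evolve with synonymous single-nucleotide changes
#' accelerated by `omega_syn`.  Dropout masks whole gene-by-taxon cells
#' with the missing symbol.  Deterministic given the scenario seed.
#'
#' @param scenario a `dp_scenario`.
#' @param seed optional override of the scenario seed.
#' @return a `dp_genetable` (gene names `gene1`, `gene2`, ...).
#' @export
simulate_alignment <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  tree <- ape::reorder.phylo(scenario$tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  model <- scenario$model
  rates <- discretize_gamma(model$alpha, model$ncat)
  genes <- list()
  for (g in seq_along(scenario$gene_lengths)) {
    len <- scenario$gene_lengths[g]
    if (scenario$mode == "codon") {
      pis <- t(node_compositions(scenario$comp, n_node, 4L))
      n_cod <- len %/% 3L
      rs <- rates[sample.int(length(rates), n_cod, replace = TRUE)]
      crm_root <- codon_rate_matrix(model$R, pis[, n_tip + 1L],
                                    scenario$omega_syn, scenario$genetic_code)
      nc <- length(crm_root$codons)
      Qs <- array(0, c(nc, nc, n_node))
      p0s <- matrix(0, nc, n_node)
      for (v in seq_len(n_node)) {
        crm <- codon_rate_matrix(model$R, pis[, v], scenario$omega_syn,
                                 scenario$genetic_code)
        Qs[, , v] <- crm$Q; p0s[, v] <- crm$p0
      }
      st <- sim_states(tree, Qs, p0s, p0s[, n_tip + 1L], rs, tree$tip.label)
      chars <- crm_root$codons[st]
      mat <- matrix("", n_tip, len, dimnames = list(tree$tip.label, NULL))
      for (k in 1:3)
        mat[, seq(k, len, by = 3)] <- substr(matrix(chars, n_tip), k, k)
      aln <- alignment(mat, alphabet = "nucleotide", codon = TRUE)
    } else {
      S <- model$S
      pis <- t(node_compositions(scenario$comp, n_node, S))
      rs <- rates[sample.int(length(rates), len, replace = TRUE)]
      Qs <- array(0, c(S, S, n_node))
      for (v in seq_len(n_node)) Qs[, , v] <- build_rate_matrix(model$R, pis[, v])
      st <- sim_states(tree, Qs, pis, pis[, n_tip + 1L], rs, tree$tip.label)
      symbols <- if (S == 4L) NUC_CORE else AA_CORE
      mat <- matrix(symbols[st], n_tip, len,
                    dimnames = list(tree$tip.label, NULL))
      aln <- alignment(mat, alphabet = if (S == 4L) "nucleotide" else "amino_acid",
                       codon = scenario$mode == "nucleotide" && len %% 3L == 0L)
    }
    # per-gene taxon dropout
    if (scenario$dropout > 0) {
      drop <- runif(n_tip) < scenario$dropout
      if (all(drop)) drop[sample.int(n_tip, 1L)] <- FALSE
      aln$mat[drop, ] <- MISSING
    }
    genes[[paste0("gene", g)]] <- aln
  }
  gene_table(genes, taxa = tree$tip.label)
}

#' Compositional-attraction scenario builder
#'
#' Four monophyletic groups on the known rooted topology
#' `((A,B),(C,D))`; the tips of the two non-sister groups B and D receive
#' a shared GC-rich composition, the convex combination
#' `(1 - s) * pi_base + s * pi_biased` with `s = bias_strength`, while all
#' other nodes keep the AT-rich base composition.  Long terminal branches
#' into the biased groups (0.8 expected substitutions/site, versus 0.2
#' elsewhere and a 0.1 internal branch) let their states drift toward the
#' biased equilibrium, mimicking convergent composition bias on saturated
#' non-sister lineages.  The generating split joins groups A and B; the
#' "attractive" wrong split joins B and D.
#'
#' @param n_taxa_per_group taxa per group (>= 1; groups are single tips or
#'   rake-like subtrees).
#' @param bias_strength mixing weight in `[0, 1]`.
#' @param seed scenario seed.
#' @param n_sites total sites (single gene).
#' @param alpha gamma shape of the generating model.
#' @return a `dp_scenario` with extra fields `groups`, `true_clade`
#'   (taxa of A+B) and `attraction_clade` (taxa of B+D).
#' @export
make_attraction_scenario <- function(n_taxa_per_group = 1, bias_strength = 0.8,
                                     seed = 1L, n_sites = 5000L, alpha = 1) {
  if (bias_strength < 0 || bias_strength > 1)
    stop("bias_strength must be in [0, 1]")
  k <- n_taxa_per_group
  grp <- function(g) paste0(g, seq_len(k))
  groups <- lapply(c(A = "A", B = "B", C = "C", D = "D"), grp)
  subtree <- function(tips, bl) {
    if (length(tips) == 1L) return(sprintf("%s:%.4f", tips, bl))
    inner <- paste(sprintf("%s:%.4f", tips, 0.05), collapse = ",")
    sprintf("(%s):%.4f", inner, bl)
  }
  t_biased <- 0.8; t_plain <- 0.2
  nwk <- sprintf("((%s,%s):0.05,(%s,%s):0.05);",
                 subtree(groups$A, t_plain), subtree(groups$B, t_biased),
                 subtree(groups$C, t_plain), subtree(groups$D, t_biased))
  tree <- ape::read.tree(text = nwk)
  tree <- ape::reorder.phylo(tree, "postorder")
  pi_base <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  pi_biased <- c(A = 0.05, C = 0.45, G = 0.45, T = 0.05)
  pi_mix <- (1 - bias_strength) * pi_base + bias_strength * pi_biased
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  pimat <- matrix(pi_base, n_node, 4, byrow = TRUE)
  biased_tips <- match(c(groups$B, groups$D), tree$tip.label)
  pimat[biased_tips, ] <- matrix(pi_mix, length(biased_tips), 4, byrow = TRUE)
  comp <- composition_ndch2(pimat)
  model <- substitution_model(alpha = alpha, ncat = 4L, states = "nucleotide")
  sc <- simulation_scenario(tree, comp, model, mode = "nucleotide",
                            gene_lengths = as.integer(n_sites), seed = seed)
  sc$groups <- groups
  sc$true_clade <- c(groups$A, groups$B)
  sc$attraction_clade <- c(groups$B, groups$D)
  stopifnot(!setequal(sc$true_clade, sc$attraction_clade))
  sc
}
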
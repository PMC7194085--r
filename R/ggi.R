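# Gene-genealogy interrogation: enumerate resolved constraint topologies on
# named groups, constrained ML hill-climbing, multiscale RELL bootstrap
# with the AU test, and the per-gene monophyly screen.

#' Enumerate all resolved unrooted topologies on named groups
#'
#' Recursive edge-insertion; the count follows the double-factorial law
#' `(2g - 5)!!` (15 topologies for the five-group case).
#'
#' @param groups named list mapping group name to its taxa (or a character
#'   vector of group names).
#' @return list of `dp_constraint` objects, each with a group-level
#'   `ape::phylo` (`tree`) and the expansion map (`groups`).
#' @export
enumerate_group_topologies <- function(groups) {
  if (is.character(groups)) groups <- setNames(as.list(groups), groups)
  g <- length(groups)
  if (g < 3) stop("need at least 3 groups")
  nms <- names(groups)
  # grow unrooted topologies by inserting leaf i on every edge
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);", nms[1], nms[2], nms[3]))
  trees <- list(base)
  for (i in seq.int(4, g, length.out = max(0, g - 3))) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(e) bind_leaf(tr, nms[i], e))
    }), recursive = FALSE)
  }
  lapply(trees, function(tr)
    structure(list(tree = tr, groups = groups), class = "dp_constraint"))
}

# insert a new leaf in the middle of edge e of an unrooted phylo
bind_leaf <- function(tr, label, e) {
  nwk <- ape::write.tree(tr)
  tr2 <- ape::read.tree(text = nwk) # private copy
  n_tip <- length(tr2$tip.label)
  par <- tr2$edge[e, 1]; chi <- tr2$edge[e, 2]
  # renumber: new tip gets id n_tip+1, so bump all node ids > n_tip
  edge <- tr2$edge
  edge[edge > n_tip] <- edge[edge > n_tip] + 1L
  new_tip <- n_tip + 1L
  new_node <- n_tip + 1L + tr2$Nnode + 1L
  epar <- edge[e, 1]; echi <- edge[e, 2]
  edge[e, ] <- c(epar, new_node)
  edge <- rbind(edge, c(new_node, echi), c(new_node, new_tip))
  out <- list(edge = edge, tip.label = c(tr2$tip.label, label),
              Nnode = tr2$Nnode + 1L)
  class(out) <- "phylo"
  out <- ape::read.tree(text = ape::write.tree(out)) # canonicalise
  out
}

#' @export
print.dp_constraint <- function(x, ...) {
  cat("<dp_constraint>", ape::write.tree(x$tree), "\n")
  invisible(x)
}

# do all groups form monophyletic clades (as unrooted splits) on tree?
groups_monophyletic <- function(tree, groups, taxa_ref) {
  keys <- tree_splits(tree, taxa_ref)
  all(vapply(groups, function(tx) {
    if (length(tx) <= 1 || length(tx) >= length(taxa_ref) - 1) return(TRUE)
    split_key(tx, taxa_ref) %in% keys
  }, TRUE))
}

# full compatibility: group monophyly AND the backbone (group-level)
# topology of the constraint, expanded to taxon splits
constraint_compatible <- function(tree, constraint, taxa_ref) {
  if (!groups_monophyletic(tree, constraint$groups, taxa_ref)) return(FALSE)
  keys <- tree_splits(tree, taxa_ref)
  gref <- sort(names(constraint$groups))
  gkeys <- tree_splits(constraint$tree, gref)
  for (gk in gkeys) {
    side <- gref[strsplit(gk, "")[[1]] == "1"]
    tx <- unlist(constraint$groups[side])
    if (!(split_key(tx, taxa_ref) %in% keys)) return(FALSE)
  }
  TRUE
}

# expand a group-level constraint into a full starting tree with random
# within-group resolutions and random backbone branch lengths
expand_constraint <- function(constraint, bl_mean = 0.1) {
  sub <- vapply(names(constraint$groups), function(g) {
    tx <- constraint$groups[[g]]
    if (length(tx) == 1L) return(sprintf("%s:%.5f", tx, rexp(1, 1 / bl_mean)))
    tr <- random_topology(tx, bl_mean)
    sub_nwk <- ape::write.tree(tr)
    sub("\\);$", sprintf("):%.5f", rexp(1, 1 / bl_mean)), sub_nwk)
  }, "")
  nwk <- ape::write.tree(constraint$tree)
  for (g in names(sub)) {
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", g, "(?![A-Za-z0-9_])"),
               sub[[g]], nwk, perl = TRUE)
  }
  tr <- ape::read.tree(text = nwk)
  tr$edge.length[is.na(tr$edge.length) | tr$edge.length <= 0] <-
    rexp(sum(is.na(tr$edge.length) | tr$edge.length <= 0), 1 / bl_mean)
  # root arbitrarily on the first group's subtree edge to get a rooted
  # binary representation for the likelihood engine
  ape::reorder.phylo(force_binary_rooted(tr), "postorder")
}

force_binary_rooted <- function(tr) {
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  }
  tr <- ape::multi2di(tr, random = FALSE)
  zero <- is.na(tr$edge.length) | tr$edge.length <= 0
  tr$edge.length[zero] <- 1e-4
  tr
}

#' Constrained maximum-likelihood search
#'
#' Hill-climb over trees compatible with a group-level constraint: NNI
#' rearrangements are accepted only when every group stays monophyletic,
#' branch lengths are optimised one at a time by Brent line search and the
#' gamma shape by bounded line search, cycled until the log-likelihood
#' gain falls below `tol`.  Repeated from `n_starts` random within-group
#' resolutions; compositions are empirical, exchangeabilities fixed at the
#' supplied model.
#'
#' @param gene_aln a `dp_alignment` covering all group taxa.
#' @param constraint a `dp_constraint`.
#' @param model a `dp_submodel`.
#' @param n_starts random restarts (paper-scale default 20; reduce for
#'   small problems).
#' @param seed RNG seed.
#' @param tol log-likelihood convergence tolerance.
#' @param optimize_alpha also optimise the gamma shape.
#' @return list with `tree`, `logL`, `site_loglik` and `alpha`.
#' @export
constrained_ml_search <- function(gene_aln, constraint, model, n_starts = 20L,
                                  seed = 1L, tol = 1e-4,
                                  optimize_alpha = TRUE) {
  set.seed(seed)
  taxa <- unlist(constraint$groups)
  missing <- setdiff(taxa, aln_taxa(gene_aln))
  if (length(missing))
    stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  taxa_ref <- sort(taxa)
  ld <- make_lik_data(gene_aln, taxa)
  emp <- empirical_composition(gene_aln)
  comp <- composition_cv1(emp)
  best <- NULL
  for (s in seq_len(n_starts)) {
    tr <- expand_constraint(constraint)
    res <- optimize_tree(ld, tr, model, comp, constraint, taxa_ref, tol,
                         optimize_alpha)
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  fin <- lik_eval(ld, best$tree, best$model, comp, per_site = TRUE)
  list(tree = best$tree, logL = best$logL, site_loglik = fin$per_site,
       alpha = best$model$alpha)
}

optimize_tree <- function(ld, tree, model, comp, constraint, taxa_ref, tol,
                          optimize_alpha, max_cycles = 20L) {
  mdl <- list(R = model$R, alpha = model$alpha, ncat = model$ncat, S = model$S)
  cur <- lik_eval(ld, tree, mdl, comp)$total
  for (cyc in seq_len(max_cycles)) {
    prev <- cur
    # branch lengths, one Brent search each
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tr2 <- tree; tr2$edge.length[e] <- t
        lik_eval(ld, tr2, mdl, comp)$total
      }
      op <- optimize(f, interval = c(1e-7, 10), maximum = TRUE, tol = 1e-5)
      if (op$objective > cur) {
        tree$edge.length[e] <- op$maximum; cur <- op$objective
      }
    }
    if (optimize_alpha) {
      g <- function(a) {
        m2 <- mdl; m2$alpha <- a
        lik_eval(ld, tree, m2, comp)$total
      }
      op <- optimize(g, interval = c(0.05, 50), maximum = TRUE, tol = 1e-4)
      if (op$objective > cur) { mdl$alpha <- op$maximum; cur <- op$objective }
    }
    # within-constraint NNI sweep (first improvement)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (rep in seq_len(8L)) {
        cand <- nni_propose(tree)
        if (!constraint_compatible(cand, constraint, taxa_ref)) next
        l2 <- lik_eval(ld, cand, mdl, comp)$total
        if (l2 > cur + 1e-9) {
          tree <- cand; cur <- l2; improved <- TRUE; break
        }
      }
    }
    if (cur - prev < tol) break
  }
  list(tree = tree, logL = cur, model = mdl)
}

#' Multiscale RELL bootstrap and the approximately unbiased test
#'
#' For each scale factor r, `n_reps` resamples of `round(r * n_sites)`
#' site columns (with replacement) are scored per topology by the summed
#' resampled log-likelihoods; the per-topology best-count proportions
#' BP(r) are probit-transformed and regressed on `(sqrt(r), 1/sqrt(r))`
#' by weighted least squares (binomial variance weights), giving a signed
#' distance d and curvature c; `p_AU = 1 - Phi(d - c)`.  Topologies whose
#' BP is degenerate (0 or 1 at every scale) get p clamped to 0 or 1 with a
#' flag.
#'
#' @param m topologies x sites matrix of per-site log-likelihoods (rows
#'   named by topology).
#' @param scales bootstrap scale factors (default 0.5 to 1.4 by 0.1).
#' @param n_reps replicates per scale (>= 100; 10000 for paper-scale runs).
#' @param seed RNG seed.
#' @return `dp_auresult`: data.frame `table` (topology, p_au, bp1 = raw
#'   scale-1 proportion, flagged), matrix `bp` (topology x scale), fitted
#'   `d` and `ccurv`.
#' @export
au_test <- function(m, scales = seq(0.5, 1.4, by = 0.1), n_reps = 1000L,
                    seed = 1L) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (n_reps < 100) stop("n_reps < 100 gives an unstable AU fit")
  if (any(!is.finite(m))) stop("site log-likelihood matrix has non-finite entries")
  set.seed(seed)
  n_topo <- nrow(m); n_sites <- ncol(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("topology", seq_len(n_topo))
  bp <- matrix(0, n_topo, length(scales),
               dimnames = list(labels, sprintf("r%.1f", scales)))
  for (k in seq_along(scales)) {
    nsub <- max(1L, round(scales[k] * n_sites))
    counts <- rmultinom(n_reps, nsub, rep(1 / n_sites, n_sites))
    tot <- m %*% counts # n_topo x n_reps
    best <- apply(tot, 2, function(x) {
      w <- which(x == max(x))
      if (length(w) > 1L) w <- sample(w, 1L)
      w
    })
    bp[, k] <- tabulate(best, n_topo) / n_reps
  }
  d <- ccurv <- p_au <- numeric(n_topo)
  flagged <- logical(n_topo)
  for (t in seq_len(n_topo)) {
    b <- bp[t, ]
    usable <- b > 0 & b < 1
    if (sum(usable) < 2) {
      p_au[t] <- if (mean(b) > 0.5) 1 else 0
      d[t] <- ccurv[t] <- NA
      flagged[t] <- TRUE
      next
    }
    r <- scales[usable]
    z <- qnorm(1 - b[usable])
    w <- n_reps * dnorm(z)^2 / (b[usable] * (1 - b[usable]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- lm.wfit(X, z, w)
    d[t] <- fit$coefficients[1]
    ccurv[t] <- fit$coefficients[2]
    p_au[t] <- 1 - pnorm(d[t] - ccurv[t])
  }
  structure(list(table = data.frame(topology = labels, p_au = p_au,
                                    bp1 = bp[, which.min(abs(scales - 1))],
                                    flagged = flagged,
                                    stringsAsFactors = FALSE),
                 bp = bp, d = d, ccurv = ccurv, scales = scales,
                 n_reps = n_reps, seed = seed),
            class = "dp_auresult")
}

#' @export
print.dp_auresult <- function(x, ...) {
  cat("<dp_auresult>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-gene monophyly screen
#'
#' A gene is kept when at least one constraint topology has an AU p-value
#' greater than or equal to `alpha` (the "equal or greater" rule), and
#' flagged aberrant otherwise.
#'
#' @param au a `dp_auresult` (or a bare numeric p-value vector).
#' @param alpha significance level (default 0.05).
#' @return list with `keep` (logical), `best_topology`, `p_values`.
#' @export
monophyly_screen <- function(au, alpha = 0.05) {
  p <- if (inherits(au, "dp_auresult")) setNames(au$table$p_au, au$table$topology)
       else au
  list(keep = any(p >= alpha),
       best_topology = names(p)[which.max(p)],
       p_values = p)
}

#' Run the full GGI screen for one gene
#'
#' Constrained ML for every enumerated group topology, the AU test on the
#' stacked per-site log-likelihoods, and the keep/flag decision.
#'
#' @param gene_aln a `dp_alignment`.
#' @param groups named list group -> taxa.
#' @param model a `dp_submodel`.
#' @param n_starts,seed,n_reps,scales as in [constrained_ml_search()] /
#'   [au_test()].
#' @param alpha screen significance level.
#' @return list with `au` (a `dp_auresult`), `screen`, `logL` per topology,
#'   `site_loglik` matrix.
#' @export
ggi_screen_gene <- function(gene_aln, groups, model, n_starts = 5L, seed = 1L,
                            n_reps = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                            alpha = 0.05) {
  topos <- enumerate_group_topologies(groups)
  site_ll <- NULL
  logL <- numeric(length(topos))
  for (i in seq_along(topos)) {
    fit <- constrained_ml_search(gene_aln, topos[[i]], model,
                                 n_starts = n_starts, seed = seed + i)
    logL[i] <- fit$logL
    site_ll <- rbind(site_ll, fit$site_loglik)
  }
  rownames(site_ll) <- paste0("T", seq_along(topos))
  au <- au_test(site_ll, scales = scales, n_reps = n_reps, seed = seed)
  list(au = au, screen = monophyly_screen(au, alpha), logL = logL,
       site_loglik = site_ll, constraints = topos)
}
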
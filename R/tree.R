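# Rooted-binary tree utilities on top of ape::phylo: split extraction,
# NNI rearrangement, random topologies, consensus construction from splits.

#' Random rooted binary topology with exponential branch lengths
#'
#' @param taxa character vector of tip labels.
#' @param bl_mean mean of the exponential branch-length draw.
#' @return an `ape::phylo`.
#' @export
random_topology <- function(taxa, bl_mean = 0.1) {
  n <- length(taxa)
  if (n < 2) stop("need >= 2 taxa")
  tr <- ape::rtree(n, rooted = TRUE, tip.label = sample(taxa))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / bl_mean)
  tr$node.label <- NULL
  tr
}

# Unrooted bipartitions of a rooted binary tree, canonicalised against a
# reference taxon ordering: each split is a 0/1 string over `taxa_ref`
# with the side containing taxa_ref[1] set to 0.  Trivial splits excluded.
tree_splits <- function(tree, taxa_ref = sort(tree$tip.label)) {
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  memb <- matrix(FALSE, n_node, length(taxa_ref))
  tipidx <- match(tree$tip.label, taxa_ref)
  for (i in seq_len(n_tip)) memb[i, tipidx[i]] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    memb[p, ] <- memb[p, ] | memb[c, ]
  }
  internal <- (n_tip + 1L):n_node
  keys <- character(0)
  for (v in internal) {
    m <- memb[v, ]
    sz <- sum(m)
    if (sz <= 1L || sz >= length(taxa_ref) - 1L) next
    if (m[1]) m <- !m
    keys <- c(keys, paste(as.integer(m), collapse = ""))
  }
  unique(keys)
}

#' Write / read a tree with node composition annotations
#'
#' Newick dialect with bracketed comment blocks in the node-label slot:
#' `[&pi=0.3|0.2|0.2|0.3]` after each node (and tip) carries that node's
#' composition vector, in state order (ACGT for nucleotides, alphabetical
#' one-letter codes for amino acids).  `read_annotated_tree()` returns the
#' tree plus a `dp_composition` in NDCH2 form (one vector per node).
#'
#' @param tree an `ape::phylo`.
#' @param comp a `dp_composition`.
#' @param path file path.
#' @return the path (writer) or `list(tree, comp)` (reader).
#' @export
write_annotated_tree <- function(tree, comp, path) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  S <- if (comp$mode == "CV1") length(comp$pi) else
    ncol(comp$pis %||% comp$pimat)
  pm <- node_compositions(comp, n_node, S)
  ann <- apply(pm, 1, function(p)
    sprintf("[&pi=%s]", paste(formatC(p, digits = 6, format = "g"),
                              collapse = "|")))
  tr2 <- tree
  tr2$tip.label <- paste0(tree$tip.label, ann[seq_len(n_tip)])
  tr2$node.label <- ann[(n_tip + 1L):n_node]
  writeLines(ape::write.tree(tr2), path)
  invisible(path)
}

#' @rdname write_annotated_tree
#' @export
read_annotated_tree <- function(path) {
  txt <- readLines(path, n = 1L)
  # protect the annotation blocks from the newick parser
  txt2 <- gsub("\\[&pi=([^]]*)\\]", "@@\\1@@", txt)
  txt2 <- gsub("\\|", "%", txt2)
  tree <- ape::read.tree(text = txt2)
  n_tip <- length(tree$tip.label)
  pull <- function(lbl) {
    m <- regmatches(lbl, regexec("@@([^@]*)@@", lbl))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "%", fixed = TRUE)[[1]])
  }
  tips <- lapply(tree$tip.label, pull)
  nodes <- lapply(tree$node.label, pull)
  tree$tip.label <- sub("@@.*$", "", tree$tip.label)
  tree$node.label <- NULL
  pm <- do.call(rbind, c(tips, nodes))
  pm <- pm / rowSums(pm)
  list(tree = tree, comp = composition_ndch2(pm))
}

# per-edge canonical identity: the sorted tip set below the edge's child;
# lines up branches across samples that share a rooted topology
edge_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  keys <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
    keys[e] <- paste(sort(below[[c]]), collapse = ",")
  }
  keys
}

# canonical key for a clade given as taxon names
split_key <- function(clade, taxa_ref) {
  m <- taxa_ref %in% clade
  if (!any(m) || all(m)) stop("split must be a proper subset of the taxa")
  if (m[1]) m <- !m
  paste(as.integer(m), collapse = "")
}

# All NNI neighbours arise from swapping, across an internal edge (u,v),
# one child subtree of v with v's sibling.  Performed by exchanging the
# child endpoints of the two edges; branch lengths stay with their edges.
# Returns the rearranged tree plus the incident nodes (u, v) and the index
# of the chosen internal edge, so callers can couple further updates to
# the rearrangement (see the MCMC "jolt" move).
nni_propose_full <- function(tree) {
  n_tip <- length(tree$tip.label)
  cand <- which(tree$edge[, 2] > n_tip) # edges into internal nodes
  if (!length(cand)) return(list(tree = tree, u = NA, v = NA, edge = NA))
  e <- cand[sample.int(length(cand), 1L)]
  u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
  sibs <- tree$edge[tree$edge[, 1] == u & tree$edge[, 2] != v, 2]
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  if (!length(sibs) || length(kids) < 2)
    return(list(tree = tree, u = NA, v = NA, edge = NA))
  w <- if (length(sibs) == 1L) sibs else sibs[sample.int(length(sibs), 1L)]
  a <- kids[sample.int(length(kids), 1L)]
  ew <- which(tree$edge[, 1] == u & tree$edge[, 2] == w)
  ea <- which(tree$edge[, 1] == v & tree$edge[, 2] == a)
  tree$edge[ew, 2] <- a
  tree$edge[ea, 2] <- w
  attr(tree, "order") <- NULL # edge surgery invalidates ape's order cache
  tree <- ape::reorder.phylo(tree, "postorder")
  e2 <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)
  list(tree = tree, u = u, v = v, edge = e2)
}

nni_propose <- function(tree) nni_propose_full(tree)$tree

# Build a rooted tree (as newick text, then parsed) from a laminar set of
# clades; each clade annotated with its frequency as a node label.
build_tree_from_clades <- function(clades, freqs, taxa) {
  if (length(clades)) {
    o <- order(vapply(clades, length, 1L), decreasing = TRUE)
    clades <- clades[o]; freqs <- freqs[o]
  }
  grow <- function(taxset, cl, fr) {
    inside <- vapply(cl, function(x) all(x %in% taxset), TRUE)
    cl <- cl[inside]; fr <- fr[inside]
    parts <- list(); labels <- c()
    used <- character(0)
    for (i in seq_along(cl)) {
      if (any(cl[[i]] %in% used)) next
      sub <- grow(cl[[i]], cl[-i], fr[-i])
      parts <- c(parts, sprintf("%s%s", sub, ""))
      labels <- c(labels, fr[i])
      used <- c(used, cl[[i]])
      names(parts)[length(parts)] <- "clade"
    }
    singles <- setdiff(taxset, used)
    txt <- c(unlist(Map(function(p, f) paste0(p, f),
                        parts, formatC(labels, format = "g"))),
             singles)
    paste0("(", paste(txt, collapse = ","), ")")
  }
  # drop clades equal to the full set (they only label the root)
  proper <- vapply(clades, function(x) length(x) < length(taxa), TRUE)
  nwk <- paste0(grow(taxa, clades[proper], freqs[proper]), ";")
  ape::read.tree(text = nwk)
}
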
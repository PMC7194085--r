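# Substitution models: exchangeabilities, per-node composition vectors,
# discrete-gamma rates, rate-matrix construction and CTMC transition kernels.

PAML_AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct a substitution model
#'
#' A reversible model is the pair (R, pi) of symmetric exchangeabilities and
#' a composition vector; compositions are supplied separately (they are the
#' tree-heterogeneous part, see [composition_cv1()] and friends).  `R` has a
#' zero diagonal and is normalised to sum 1 over the upper triangle for
#' identifiability.
#'
#' @param R symmetric non-negative exchangeability matrix (default: all
#'   equal, the Jukes-Cantor / F81 limit), 4x4 for nucleotides, 20x20 for
#'   amino acids.
#' @param alpha gamma shape for among-site rate variation (> 0).
#' @param ncat number of discrete gamma categories (default 4; 1 = no rate
#'   variation).
#' @param states `"nucleotide"` or `"amino_acid"`.
#' @param name label, e.g. `"GTR"` or an empirical matrix name.
#' @return object of class `dp_submodel`.
#' @export
substitution_model <- function(R = NULL, alpha = 1, ncat = 4L,
                               states = c("nucleotide", "amino_acid"),
                               name = "GTR") {
  states <- match.arg(states)
  S <- if (states == "nucleotide") 4L else 20L
  if (is.null(R)) {
    R <- matrix(1, S, S); diag(R) <- 0
  }
  stopifnot(nrow(R) == S, ncol(R) == S, all(R >= 0),
            isTRUE(all.equal(R, t(R))), alpha > 0, ncat >= 1)
  diag(R) <- 0
  R <- R / sum(R[upper.tri(R)])
  structure(list(R = R, alpha = alpha, ncat = as.integer(ncat),
                 states = states, S = S, name = name),
            class = "dp_submodel")
}

#' @export
print.dp_submodel <- function(x, ...) {
  cat(sprintf("<dp_submodel> %s, %d states, alpha=%.3g, %d gamma categories\n",
              x$name, x$S, x$alpha, x$ncat))
  invisible(x)
}

#' Build a scaled GTR-style rate matrix
#'
#' `Q[i,j] = R[i,j] * pi[j]` off-diagonal, rows summing to zero, scaled so
#' that the expected substitution rate at stationarity is one
#' (`-sum(pi * diag(Q)) == 1`), so branch lengths are expected
#' substitutions per site under that composition.
#'
#' @param R symmetric exchangeability matrix.
#' @param pi composition vector on the simplex (all entries > 0).
#' @return rate matrix Q.
#' @export
build_rate_matrix <- function(R, pi) {
  if (any(pi <= 0)) stop("composition entries must be > 0")
  pi <- pi / sum(pi)
  Q <- R * rep(pi, each = nrow(R))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  Q / beta
}

#' Discrete-gamma rate categories (category means)
#'
#' Equiprobable categories of a Gamma(shape = alpha, mean = 1)
#' distribution, each represented by its conditional mean, renormalised so
#' the category mean is exactly one.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of k rates with mean 1.
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # conditional means via the incomplete-gamma identity:
  # int_a^b x dGamma(a,r) = (shape/rate) * (F_{shape+1}(b) - F_{shape+1}(a))
  pg <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  rates <- k * diff(pg)
  rates / mean(rates)
}

#' Transition probability matrix P = exp(Q * t * rate)
#'
#' Uses the symmetrised eigendecomposition when the stationary composition
#' is supplied (reversible Q), a general Pade matrix exponential otherwise.
#'
#' @param Q rate matrix.
#' @param t branch length (>= 0, finite).
#' @param rate rate multiplier (> 0).
#' @param pi stationary composition of Q (optional, numerical fast path).
#' @return stochastic matrix P.
#' @export
transition_probabilities <- function(Q, t, rate = 1, pi = NULL) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  stopifnot(rate > 0)
  if (t == 0) return(diag(nrow(Q)))
  if (!is.null(pi)) {
    d <- sqrt(pi)
    B <- Q * (d %o% (1 / d))
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    P <- (e$vectors %*% (exp(e$values * t * rate) * t(e$vectors))) *
      ((1 / d) %o% d)
  } else {
    P <- cpp_expmat(Q * (t * rate))
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- composition attachments -------------------------------------------

#' Composition attachments for a tree
#'
#' Three modes of among-lineage composition heterogeneity: `CV1` (one
#' vector shared by the whole tree), `NDCH-k` (k shared vectors plus a
#' per-node assignment) and `NDCH2` (one vector per node).  The vector
#' attached to a node governs the branch leading into that node; the root's
#' vector is the root state distribution.
#'
#' @param pi composition vector (simplex).
#' @return object of class `dp_composition`.
#' @export
composition_cv1 <- function(pi) {
  new_composition("CV1", pi = check_simplex(pi))
}

#' @rdname composition_cv1
#' @param pis k x S matrix of composition vectors (rows are simplex points).
#' @param assignment integer vector over all node ids (tips first, as in
#'   `ape::phylo` numbering) giving each node's vector index in `1..k`.
#' @export
composition_ndch <- function(pis, assignment) {
  pis <- t(apply(pis, 1, check_simplex))
  stopifnot(all(assignment >= 1), all(assignment <= nrow(pis)))
  new_composition("NDCH", pis = pis, assignment = as.integer(assignment))
}

#' @rdname composition_cv1
#' @param pimat n_nodes x S matrix, one composition vector per node id.
#' @export
composition_ndch2 <- function(pimat) {
  pimat <- t(apply(pimat, 1, check_simplex))
  new_composition("NDCH2", pimat = pimat)
}

new_composition <- function(mode, ...) {
  structure(c(list(mode = mode), list(...)), class = "dp_composition")
}

check_simplex <- function(pi) {
  if (any(pi <= 0)) stop("composition entries must be > 0")
  pi / sum(pi)
}

# Resolve any composition mode to an n_node x S matrix indexed by node id.
node_compositions <- function(comp, n_nodes, S) {
  switch(comp$mode,
    CV1 = matrix(comp$pi, n_nodes, S, byrow = TRUE),
    NDCH = {
      if (length(comp$assignment) != n_nodes)
        stop("NDCH assignment must cover all ", n_nodes, " nodes")
      comp$pis[comp$assignment, , drop = FALSE]
    },
    NDCH2 = {
      if (nrow(comp$pimat) != n_nodes)
        stop("NDCH2 requires one composition per node (", n_nodes, " needed, ",
             nrow(comp$pimat), " attached)")
      comp$pimat
    },
    stop("unknown composition mode"))
}

# ---- empirical amino-acid models ---------------------------------------

#' Read a PAML-format empirical amino-acid exchangeability matrix
#'
#' PAML `.dat` layout: 19 lower-triangle rows of exchangeabilities followed
#' by a line (or lines) of 20 equilibrium frequencies, amino acids in PAML
#' order (ARNDCQEGHILKMFPSTWYV).  Returned in this package's alphabetical
#' order (ACDEFGHIKLMNPQRSTVWY).
#'
#' @param path path to the `.dat` file.
#' @return list with `R` (20x20 symmetric) and `freq` (length 20).
#' @export
read_paml_matrix <- function(path) {
  toks <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE,
               nmax = 190 + 20)
  if (length(toks) < 210) stop("not a PAML rate file (need 190 + 20 numbers): ", path)
  R <- matrix(0, 20, 20, dimnames = list(PAML_AA_ORDER, PAML_AA_ORDER))
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) { R[i, j] <- toks[k]; k <- k + 1 }
  R <- R + t(R)
  freq <- toks[191:210]
  names(freq) <- PAML_AA_ORDER
  ord <- AA_CORE
  list(R = R[ord, ord], freq = freq[ord] / sum(freq))
}

#' Empirical amino-acid model by name
#'
#' Exchangeabilities are taken from the `phangorn` package's built-in model
#' set (JTT, LG, WAG, ...); matrices not shipped there (e.g. stmtREV) can
#' be supplied as a PAML `.dat` file via `path`.
#'
#' @param name model name as known to `phangorn` (ignored when `path` given).
#' @param path optional PAML `.dat` file with a user-supplied matrix.
#' @param alpha,ncat gamma shape and category count.
#' @return a `dp_submodel` with attribute `freq` (the matrix's own
#'   equilibrium frequencies, available as a composition starting point).
#' @export
empirical_aa_model <- function(name = "JTT", path = NULL, alpha = 1, ncat = 4L) {
  if (!is.null(path)) {
    m <- read_paml_matrix(path)
  } else {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("phangorn is required for built-in empirical matrices")
    known <- get(".aamodels", envir = asNamespace("phangorn"))
    if (!name %in% known) stop("unknown empirical model: ", name)
    mod <- get(paste0(".", name), envir = asNamespace("phangorn"))
    # phangorn stores the lower triangle (190 rates) and frequencies in
    # PAML amino-acid order
    R <- matrix(0, 20, 20, dimnames = list(PAML_AA_ORDER, PAML_AA_ORDER))
    R[lower.tri(R)] <- mod$Q
    R <- R + t(R)
    ord <- AA_CORE
    m <- list(R = R[ord, ord],
              freq = setNames(as.numeric(mod$bf), PAML_AA_ORDER)[ord])
  }
  out <- substitution_model(R = m$R, alpha = alpha, ncat = ncat,
                            states = "amino_acid", name = name)
  attr(out, "freq") <- m$freq
  out
}
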
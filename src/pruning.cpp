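// Felsenstein pruning with per-node rate matrices (one Q per node, the
// branch into a node uses that node's Q) and a discrete-gamma rate mixture.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_expmat(const arma::mat& A) { return expmat(A); }

// Reversible matrix exponential via symmetrised eigendecomposition.
static mat rev_expm(const mat& Q, const vec& pi, double t) {
  vec d = sqrt(pi);
  mat B = Q;
  B.each_col() %= d;
  B.each_row() /= d.t();
  B = 0.5 * (B + B.t());
  vec ev; mat V;
  eig_sym(ev, V, B);
  mat P = V * diagmat(exp(ev * t)) * V.t();
  P.each_col() /= d;
  P.each_row() %= d.t();
  P.elem(find(P < 0)).zeros();
  P.each_col() /= sum(P, 1);
  return P;
}

// Per-pattern log-likelihoods.
// edge: 2 x n_edge (parent, child), 1-based node ids, postorder
// (children before parents).  tip_partials: S x npat x n_tip cube.
// Qs: S x S x n_node cube, slice v = rate matrix governing the branch
// into node v.  pis: S x n_node composition per node (for the fast
// reversible exponential).  root_pi weights the root partials.
// [[Rcpp::export]]
arma::vec cpp_pruning(const arma::imat& edge, const arma::vec& elen,
                      int n_tip, int n_node, int root,
                      const arma::cube& tip_partials,
                      const arma::cube& Qs, const arma::mat& pis,
                      const arma::vec& root_pi, const arma::vec& rates) {
  const int S = tip_partials.n_rows;
  const int npat = tip_partials.n_cols;
  const int n_edge = edge.n_cols;
  const int ncat = rates.n_elem;

  mat catlik(npat, ncat, fill::zeros); // log-lik per pattern per category
  for (int c = 0; c < ncat; ++c) {
    std::vector<mat> partial(n_node + 1);
    std::vector<char> seen(n_node + 1, 0);
    vec scaler(npat, fill::zeros); // shared log-scaler accumulator
    for (int e = 0; e < n_edge; ++e) {
      int par = edge(0, e), chi = edge(1, e);
      mat P = rev_expm(Qs.slice(chi - 1), pis.col(chi - 1),
                       elen(e) * rates(c));
      mat down;
      if (chi <= n_tip) {
        down = P * tip_partials.slice(chi - 1);
      } else {
        // rescale completed internal partial before propagating
        mat& pc = partial[chi];
        rowvec m = max(pc, 0);
        m.elem(find(m <= 0)).ones(); // dead patterns guard
        pc.each_row() /= m;
        scaler += log(m.t());
        down = P * pc;
      }
      if (!seen[par]) { partial[par] = down; seen[par] = 1; }
      else partial[par] %= down;
    }
    vec site = (root_pi.t() * partial[root]).t();
    catlik.col(c) = log(site) + scaler;
  }
  // mix categories with equal weights (log-sum-exp)
  vec mx = max(catlik, 1);
  vec out(npat);
  for (int p = 0; p < npat; ++p) {
    double s = 0;
    for (int c = 0; c < ncat; ++c) s += std::exp(catlik(p, c) - mx(p));
    out(p) = mx(p) + std::log(s) - std::log((double)ncat);
  }
  return out;
}
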
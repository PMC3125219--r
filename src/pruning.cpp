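// Felsenstein pruning for reversible substitution models with site-class
// mixtures. States are generic (4 for nucleotides, 61 for sense codons).
// Two entry points: a generic one taking per-class spectral
// decompositions (used by the clock module), and a GY94-specific one
// that builds the codon rate matrices, their eigendecompositions and
// the mixture-level rate normalization internally (used by the site
// models, where this is the optimizer's inner loop).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Core pruning pass for one class: V, Vinv, eval define P(t); returns
// per-pattern log likelihood (with underflow rescaling).
static arma::rowvec prune_class(const arma::imat& edge,
                                const arma::vec& blen,
                                const arma::imat& tipstate,
                                const arma::mat& V, const arma::mat& Vinv,
                                const arma::vec& eval,
                                const arma::vec& rootfreq) {
  const int E = edge.n_rows;
  const int ntip = tipstate.n_rows;
  const int S = tipstate.n_cols;
  const int nstates = rootfreq.n_elem;
  int nnodes = ntip;
  for (int e = 0; e < E; ++e)
    nnodes = std::max(nnodes, std::max(edge(e, 0), edge(e, 1)));
  const int root = edge(E - 1, 0);

  std::vector<arma::mat> partial(nnodes + 1);
  std::vector<bool> init(nnodes + 1, false);
  arma::rowvec logscale(S, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    const int par = edge(e, 0), chi = edge(e, 1);
    arma::mat P = V * arma::diagmat(arma::exp(eval * blen(e))) * Vinv;
    P.elem(arma::find(P < 0)).zeros();
    arma::mat contrib(nstates, S);
    if (chi <= ntip) {
      arma::vec rs = arma::sum(P, 1);
      for (int s = 0; s < S; ++s) {
        const int st = tipstate(chi - 1, s);
        if (st == 0) contrib.col(s) = rs;  // gap/ambiguous tip state
        else contrib.col(s) = P.col(st - 1);
      }
    } else {
      contrib = P * partial[chi];
    }
    if (!init[par]) { partial[par] = contrib; init[par] = true; }
    else partial[par] %= contrib;
    if (par == root || (e % 8) == 7) {
      arma::rowvec mx = arma::max(partial[par], 0);
      mx.elem(arma::find(mx <= 0)).ones();
      partial[par].each_row() /= mx;
      logscale += arma::log(mx);
    }
  }
  arma::rowvec sitelik = rootfreq.t() * partial[root];
  arma::rowvec out(S);
  for (int s = 0; s < S; ++s)
    out(s) = std::log(std::max(sitelik(s), 1e-300)) + logscale(s);
  return out;
}

// Generic mixture interface: per-class eigendecompositions supplied.
// edge: E x 2 (parent, child), 1-based, postorder; tips 1..ntip.
// tipstate: ntip x S, 1-based state indices, 0 = missing.
// Returns K x S log site likelihoods.
// [[Rcpp::export]]
arma::mat prune_loglik_cpp(const arma::imat& edge, const arma::vec& blen,
                           const arma::imat& tipstate,
                           const arma::cube& V, const arma::cube& Vinv,
                           const arma::mat& eval,
                           const arma::vec& rootfreq) {
  const int K = V.n_slices;
  arma::mat out(K, tipstate.n_cols);
  for (int k = 0; k < K; ++k)
    out.row(k) = prune_class(edge, blen, tipstate, V.slice(k),
                             Vinv.slice(k), eval.col(k), rootfreq);
  return out;
}

// GY94 mixture: builds per-class rate matrices from the substitution
// type table (0 none/multi-nt, 1 syn tv, 2 syn ts, 3 nonsyn tv,
// 4 nonsyn ts), normalizes branch lengths by the mixture mean rate and
// runs the pruning per class. Returns K x S log site likelihoods.
// [[Rcpp::export]]
arma::mat gy94_mixture_loglik_cpp(const arma::imat& edge,
                                  const arma::vec& blen,
                                  const arma::imat& tipstate,
                                  double kappa,
                                  const arma::vec& omegas,
                                  const arma::vec& weights,
                                  const arma::vec& pi,
                                  const arma::imat& type) {
  const int K = omegas.n_elem;
  const int n = pi.n_elem;  // 61
  std::vector<arma::mat> Qs(K);
  arma::vec rates(K);
  for (int k = 0; k < K; ++k) {
    arma::mat Q(n, n, arma::fill::zeros);
    const double w = omegas(k);
    for (int i = 0; i < n; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        double m;
        switch (type(i, j)) {
          case 1: m = 1.0; break;
          case 2: m = kappa; break;
          case 3: m = w; break;
          case 4: m = w * kappa; break;
          default: m = 0.0;
        }
        const double q = m * pi(j);
        Q(i, j) = q;
        rowsum += q;
      }
      Q(i, i) = -rowsum;
    }
    rates(k) = -arma::dot(pi, Q.diag());
    Qs[k] = Q;
  }
  const double mean_rate = arma::dot(weights, rates);
  arma::vec bl = blen / std::max(mean_rate, 1e-300);

  arma::vec sp = arma::sqrt(pi);
  arma::mat out(K, tipstate.n_cols);
  for (int k = 0; k < K; ++k) {
    arma::mat Ssym = Qs[k];
    Ssym.each_col() %= sp;
    Ssym.each_row() /= sp.t();
    Ssym = (Ssym + Ssym.t()) / 2.0;
    arma::vec eval;
    arma::mat U;
    arma::eig_sym(eval, U, Ssym);
    arma::mat V = U;  V.each_col() /= sp;
    arma::mat Vinv = U.t();  Vinv.each_row() %= sp.t();
    out.row(k) = prune_class(edge, bl, tipstate, V, Vinv, eval, pi);
  }
  return out;
}
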
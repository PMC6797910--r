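#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning under the closed-form profile process, evaluated for
// every (column, profile-pair) combination in one call.
//
// postorder : node numbers (1-based), children before parents, root last
// parent    : parent node number per node (0 at the root)
// blen      : branch length above each node
// edge_class: 0 ancestral, 1 convergent, 2 transition (forced change)
// tipstates : ntip x ncols integer matrix, residues 1..20 (no gaps)
// profiles  : 20 x K frequency matrix
// beta      : per-profile rate normalization 1/(1 - sum(pi^2))
// pairs     : P x 2 (ancestral, convergent) profile indices, 1-based;
//             the root prior is the ancestral profile of the pair
//
// Under the closed form P_ij(t) = w delta_ij + (1-w) pi_j the message up an
// ordinary edge is
//   m_i = w L_i + (1 - w) (pi . L),  w = exp(-beta t),
// and up a transition edge (conditioned on at least one event)
//   m_i = pi_c . L  for all i.
//
// Returns an ncols x P matrix of log-likelihoods.
// [[Rcpp::export]]
NumericMatrix prune_loglik_cpp(IntegerVector postorder, IntegerVector parent,
                               NumericVector blen, IntegerVector edge_class,
                               IntegerMatrix tipstates, NumericMatrix profiles,
                               NumericVector beta, IntegerMatrix pairs,
                               int ntip) {
  const int n_all = parent.size();
  const int ncols = tipstates.ncol();
  const int P = pairs.nrow();
  NumericMatrix out(ncols, P);
  std::vector<double> L(static_cast<size_t>(n_all) * 20);

  for (int c = 0; c < ncols; ++c) {
    for (int p = 0; p < P; ++p) {
      const int pa = pairs(p, 0) - 1;
      const int pc = pairs(p, 1) - 1;
      double logscale = 0.0;
      bool dead = false;
      std::fill(L.begin(), L.end(), 1.0);
      for (int t = 0; t < ntip; ++t) {
        double *Lt = &L[static_cast<size_t>(t) * 20];
        for (int s = 0; s < 20; ++s) Lt[s] = 0.0;
        Lt[tipstates(t, c) - 1] = 1.0;
      }
      for (int k = 0; k < n_all; ++k) {
        const int v = postorder[k] - 1;
        double *Lv = &L[static_cast<size_t>(v) * 20];
        double mx = 0.0;
        for (int s = 0; s < 20; ++s)
          if (Lv[s] > mx) mx = Lv[s];
        if (!(mx > 0.0)) { dead = true; break; }
        for (int s = 0; s < 20; ++s) Lv[s] /= mx;
        logscale += std::log(mx);
        const int par = parent[v] - 1;
        if (par < 0) {
          const double *pi = &profiles(0, pa);
          double tot = 0.0;
          for (int s = 0; s < 20; ++s) tot += pi[s] * Lv[s];
          out(c, p) = std::log(tot) + logscale;
          break;
        }
        const int cls = edge_class[v];
        const int prof = (cls >= 1) ? pc : pa;
        const double *pi = &profiles(0, prof);
        double dot = 0.0;
        for (int s = 0; s < 20; ++s) dot += pi[s] * Lv[s];
        double *Lp = &L[static_cast<size_t>(par) * 20];
        if (cls == 2) {
          for (int s = 0; s < 20; ++s) Lp[s] *= dot;
        } else {
          const double w = std::exp(-beta[prof] * blen[v]);
          const double q = 1.0 - w;
          for (int s = 0; s < 20; ++s) Lp[s] *= w * Lv[s] + q * dot;
        }
      }
      if (dead) out(c, p) = R_NegInf;
    }
  }
  return out;
}
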
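#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein peeling for Brownian motion with independent traits and
// per-edge, per-trait variances.  `edge` must be in postorder (children
// before parents) with 1-based ape node indexing; the root is node
// n_tips + 1.  With root_mean absent, the GLS root mean is plugged in, so
// the result equals the dense multivariate-normal density with covariance
// built from shared weighted path lengths and mean equal to the GLS
// estimate, trait by trait.
// [[Rcpp::export]]
List bm_prune_cpp(IntegerMatrix edge, NumericMatrix edge_var,
                  NumericMatrix tipvals, int n_tips, int n_nodes,
                  Nullable<NumericVector> root_mean = R_NilValue) {
  const int ne = edge.nrow(), p = tipvals.ncol();
  NumericVector rm(p), rv(p), ll(p);
  bool have_mu = root_mean.isNotNull();
  NumericVector mu;
  if (have_mu) mu = NumericVector(root_mean);
  std::vector<double> m(n_nodes), V(n_nodes);
  std::vector<int> cnt(n_nodes);
  double total = 0.0;
  for (int j = 0; j < p; j++) {
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(m.begin(), m.end(), 0.0);
    std::fill(V.begin(), V.end(), 0.0);
    for (int t = 0; t < n_tips; t++) m[t] = tipvals(t, j);
    double lnl = 0.0;
    for (int e = 0; e < ne; e++) {
      int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
      double Vc = V[v] + edge_var(e, j);
      double mc = m[v];
      if (cnt[u] == 0) {
        m[u] = mc; V[u] = Vc; cnt[u] = 1;
      } else {
        double S = V[u] + Vc;
        if (S <= 0.0) { lnl = R_NegInf; break; }
        double dm = m[u] - mc;
        lnl += -0.5 * (std::log(2.0 * M_PI * S) + dm * dm / S);
        m[u] = (Vc * m[u] + V[u] * mc) / S;
        V[u] = V[u] * Vc / S;
      }
    }
    int root = n_tips;
    rm[j] = m[root]; rv[j] = V[root];
    if (R_finite(lnl)) {
      if (V[root] <= 0.0) lnl = R_NegInf;
      else {
        double mu_j = have_mu ? mu[j] : m[root];
        double dm = mu_j - m[root];
        lnl += -0.5 * (std::log(2.0 * M_PI * V[root]) + dm * dm / V[root]);
      }
    }
    ll[j] = lnl;
    total += lnl;
  }
  return List::create(_["loglik"] = total, _["per_trait"] = ll,
                      _["root_mean"] = rm, _["root_var"] = rv);
}
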
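#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Discontinuity d1(R, U o f) for every state (row) of `states`.
// states: n_states x k, integer levels 0..m-1 (0-based).
// [[Rcpp::export]]
NumericVector d_profile_cpp(IntegerMatrix states, NumericMatrix R,
                            NumericMatrix U) {
  const int ns = states.nrow(), k = states.ncol();
  NumericVector d(ns);
  for (int a = 0; a < k; ++a) {
    for (int b = a + 1; b < k; ++b) {
      const double r = R(a, b);
      const int *ca = &states(0, a), *cb = &states(0, b);
      for (int i = 0; i < ns; ++i) {
        d[i] += std::fabs(r - U(ca[i], cb[i]));
      }
    }
  }
  return d;
}

// As efe_eval_cpp below, but taking the free-parameter vector directly:
// par = (R upper triangle, U upper triangle), both in column-major
// upper-triangle order with unit diagonals implied. Avoids rebuilding
// full matrices in R for every objective evaluation.
// [[Rcpp::export]]
double efe_eval_par_cpp(IntegerMatrix states, NumericVector par, int k,
                        int m, IntegerVector obs_idx, NumericVector w,
                        double eps) {
  const int ns = states.nrow();
  const int n_r = k * (k - 1) / 2;
  // U as a full matrix for O(1) lookups
  std::vector<double> U(m * m, 1.0);
  {
    int p = n_r;
    for (int v = 1; v < m; ++v) {
      for (int u = 0; u < v; ++u) {
        const double x = par[p++];
        U[u + v * m] = x;
        U[v + u * m] = x;
      }
    }
  }
  std::vector<double> d(ns, 0.0);
  int p = 0;
  for (int b = 1; b < k; ++b) {
    for (int a = 0; a < b; ++a) {
      const double r = par[p++];
      const int *ca = &states(0, a), *cb = &states(0, b);
      for (int i = 0; i < ns; ++i) {
        d[i] += std::fabs(r - U[ca[i] + cb[i] * m]);
      }
    }
  }
  std::vector<double> sd(d);
  std::sort(sd.begin(), sd.end());
  double acc = 0.0, wsum = 0.0;
  const int no = obs_idx.size();
  for (int i = 0; i < no; ++i) {
    const double t = d[obs_idx[i]] + eps;
    const std::size_t c =
        std::upper_bound(sd.begin(), sd.end(), t) - sd.begin();
    acc += w[i] * std::log2(static_cast<double>(c));
    wsum += w[i];
  }
  return acc / wsum;
}

// Expected float entropy (bits) of weighted states under model (R, U).
// obs_idx: 0-based canonical state indices of the distinct observed states;
// w: their weights (multiplicities or probabilities). Ties in the
// accessible-set count "d <= d(f)" use absolute tolerance eps.
// [[Rcpp::export]]
double efe_eval_cpp(IntegerMatrix states, NumericMatrix R, NumericMatrix U,
                    IntegerVector obs_idx, NumericVector w, double eps) {
  NumericVector d = d_profile_cpp(states, R, U);
  std::vector<double> sd(d.begin(), d.end());
  std::sort(sd.begin(), sd.end());
  double acc = 0.0, wsum = 0.0;
  const int no = obs_idx.size();
  for (int i = 0; i < no; ++i) {
    const double t = d[obs_idx[i]] + eps;
    const std::size_t c =
        std::upper_bound(sd.begin(), sd.end(), t) - sd.begin();
    acc += w[i] * std::log2(static_cast<double>(c));
    wsum += w[i];
  }
  return acc / wsum;
}
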
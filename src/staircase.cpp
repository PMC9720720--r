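// Fast path for nested indicator-only weight matrices (staircase form):
// given sorted leading-one counts, fill the doubly stochastic P-matrix and
// reduce the per-event tallies in one pass.

#include <Rcpp.h>
using namespace Rcpp;

// counts must be sorted ascending and satisfy counts[i] >= i+1.
// vals: cross values of the pool states, in the same (sorted) row order.
// thr:  per-column crossing thresholds; durs: per-row state durations.
// [[Rcpp::export]]
List cpp_staircase_tally(IntegerVector counts, NumericVector vals,
                         NumericVector thr, NumericVector durs) {
  int n = counts.size();
  NumericMatrix P(n, n);
  std::vector<double> colspent(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int ni = counts[i];
    if (ni < i + 1) stop("staircase permanent is zero");
    double share = 1.0 / (ni - i);
    for (int j = 0; j < ni; ++j) {
      double p = (1.0 - colspent[j]) * share;
      P(i, j) = p;
      colspent[j] += p;
    }
  }
  NumericVector num(n), dur(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0, d = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = P(i, j);
      if (p == 0.0) continue;
      d += p * durs[i];
      if (vals[i] >= thr[j]) s += p;
    }
    num[j] = s; dur[j] = d;
  }
  return List::create(_["P"] = P, _["num"] = num, _["dur"] = dur);
}
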
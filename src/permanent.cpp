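// Balasubramanian-Bax-Franklin-Glynn permanent via Gray-code iteration over
// the sign vectors of the Glynn expansion:
//   perm(M) = 2^{1-n} sum_{d in {+-1}^n, d_1 = +1} (prod_i d_i) prod_j sum_i d_i M_ij
// Each Gray step flips one sign and updates the column sums in O(n).
// Accumulation in long double.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_permanent_bbfg(NumericMatrix M) {
  int n = M.nrow();
  if (n == 0) return 1.0;
  if (n == 1) return M(0, 0);
  std::vector<long double> colsum(n);
  for (int j = 0; j < n; ++j) {
    long double s = 0.0L;
    for (int i = 0; i < n; ++i) s += M(i, j);
    colsum[j] = s;
  }
  std::vector<int> delta(n, 1);
  long double total = 1.0L;
  {
    long double p = 1.0L;
    for (int j = 0; j < n; ++j) p *= colsum[j];
    total = p;
  }
  unsigned long long iters = 1ULL << (n - 1);
  unsigned long long gray_prev = 0ULL;
  int sign = 1;
  for (unsigned long long k = 1; k < iters; ++k) {
    unsigned long long gray = k ^ (k >> 1);
    unsigned long long diff = gray ^ gray_prev;
    int bit = 0;
    while (!((diff >> bit) & 1ULL)) ++bit;
    int i = bit + 1;                  // delta[0] fixed at +1
    delta[i] = -delta[i];
    sign = -sign;
    double two_d = 2.0 * delta[i];
    long double p = 1.0L;
    for (int j = 0; j < n; ++j) {
      colsum[j] += two_d * M(i, j);
      p *= colsum[j];
    }
    total += sign * p;
    gray_prev = gray;
  }
  long double val = total / (long double)std::pow(2.0L, n - 1);
  if (val < 0.0L) val = 0.0L;         // clamp float noise
  return (double)val;
}
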
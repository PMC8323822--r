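#include <Rcpp.h>
using namespace Rcpp;

// Raw linear cross-correlogram of two binned spike signals, restricted to
// lags -max_lag..max_lag (in bins). Exploits sparsity: for sorted bin
// indices bj (neuron j) and bk (neuron k), counts pairs with
// bk - bj = lag, which equals sum_t s_j(t) s_k(t + lag) for count signals.
//
// [[Rcpp::export(name = ".lag_histogram")]]
NumericVector lag_histogram(IntegerVector bj, IntegerVector bk, int max_lag) {
  NumericVector counts(2 * max_lag + 1);
  const int nj = bj.size(), nk = bk.size();
  int lo = 0;
  for (int i = 0; i < nj; ++i) {
    const int base = bj[i];
    while (lo < nk && bk[lo] < base - max_lag) ++lo;
    for (int q = lo; q < nk && bk[q] <= base + max_lag; ++q)
      counts[bk[q] - base + max_lag] += 1.0;
  }
  return counts;
}
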
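#include <Rcpp.h>
using namespace Rcpp;

// N null statistics, each the sum of m values of `tvals` drawn without
// replacement (partial Fisher-Yates on a persistent permutation; uniform
// regardless of the starting arrangement). Uses R's RNG so draws are
// reproducible under set.seed().
// [[Rcpp::export(name = ".null_sum_draws_cpp")]]
NumericVector null_sum_draws_cpp(NumericVector tvals, int m, int N) {
  int n = tvals.size();
  if (m > n) stop("m exceeds background size");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(N);
  for (int j = 0; j < N; ++j) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) {
      int r = k + (int)(unif_rand() * (n - k));
      if (r >= n) r = n - 1;
      std::swap(idx[k], idx[r]);
      s += tvals[idx[k]];
    }
    out[j] = s;
  }
  return out;
}
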
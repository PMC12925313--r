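#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Median of the first k elements of v (v is scratch; modified in place).
static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + h);
  return 0.5 * (lo + hi);
}

// Count random relabelings whose |median(A) - median(B)| reaches the
// observed absolute statistic. Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".perm_count_median_diff")]]
int perm_count_median_diff(Rcpp::NumericVector pooled, int n_a,
                           double observed_abs, int n_perm) {
  const int n = pooled.size();
  std::vector<double> pool(pooled.begin(), pooled.end());
  std::vector<double> a((size_t)n_a), b((size_t)(n - n_a));
  const double eps = 1e-12 * (1.0 + observed_abs);
  int count = 0;
  Rcpp::RNGScope scope;
  for (int it = 0; it < n_perm; ++it) {
    // partial Fisher-Yates: first n_a slots become group A
    for (int i = 0; i < n_a; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
    }
    std::copy(pool.begin(), pool.begin() + n_a, a.begin());
    std::copy(pool.begin() + n_a, pool.end(), b.begin());
    double stat = median_of(a) - median_of(b);
    if (std::fabs(stat) >= observed_abs - eps) ++count;
  }
  return count;
}
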
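#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Optimal 1-D k-means by dynamic programming over interval partitions of the
// sorted data (the 1-D k-means optimum is always an interval partition).
// D[m][i] = min cost of splitting x[0..i] into m clusters; rows are filled by
// divide-and-conquer exploiting monotonicity of the argmin, giving
// O(k n log n) overall.

namespace {

struct Prefix {
  std::vector<long double> s1, s2;
  explicit Prefix(const std::vector<double>& x) {
    const size_t n = x.size();
    s1.assign(n + 1, 0.0L);
    s2.assign(n + 1, 0.0L);
    for (size_t i = 0; i < n; ++i) {
      s1[i + 1] = s1[i] + x[i];
      s2[i + 1] = s2[i] + (long double)x[i] * x[i];
    }
  }
  // within-cluster sum of squares of x[j..i], 0-based inclusive
  long double cost(size_t j, size_t i) const {
    const long double s = s1[i + 1] - s1[j];
    const long double q = s2[i + 1] - s2[j];
    const long double m = (long double)(i - j + 1);
    long double c = q - s * s / m;
    return c > 0.0L ? c : 0.0L;
  }
};

void fill_row(size_t m, size_t lo, size_t hi, size_t opt_lo, size_t opt_hi,
              const Prefix& pf,
              const std::vector<long double>& prev,
              std::vector<long double>& cur,
              std::vector<size_t>& split) {
  if (lo > hi) return;
  const size_t mid = lo + (hi - lo) / 2;
  long double best = std::numeric_limits<long double>::infinity();
  size_t best_j = std::max(m, opt_lo);
  const size_t j_hi = std::min(mid, opt_hi);
  for (size_t j = std::max(m, opt_lo); j <= j_hi; ++j) {
    // cluster m covers x[j..mid]; previous m-1 clusters cover x[0..j-1]
    const long double c = prev[j - 1] + pf.cost(j, mid);
    if (c < best) {  // strict: earliest argmin on ties keeps monotonicity
      best = c;
      best_j = j;
    }
  }
  cur[mid] = best;
  split[mid] = best_j;
  if (mid > lo) fill_row(m, lo, mid - 1, opt_lo, best_j, pf, prev, cur, split);
  if (mid < hi) fill_row(m, mid + 1, hi, best_j, opt_hi, pf, prev, cur, split);
}

}  // namespace

// [[Rcpp::export(name = ".kmeans1d_dp")]]
List kmeans1d_dp(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1) stop("k must be >= 1");
  if (n < k) stop("need at least k observations");

  std::vector<size_t> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return x[a] < x[b]; });
  std::vector<double> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = x[ord[i]];

  Prefix pf(xs);
  std::vector<long double> prev(n), cur(n);
  std::vector<std::vector<size_t>> splits(k, std::vector<size_t>(n, 0));
  for (int i = 0; i < n; ++i) prev[i] = pf.cost(0, i);
  for (int m = 1; m < k; ++m) {
    fill_row((size_t)m, (size_t)m, (size_t)(n - 1), (size_t)m,
             (size_t)(n - 1), pf, prev, cur, splits[m]);
    for (int i = 0; i < m; ++i) cur[i] = 0.0L;  // unused below the diagonal
    std::swap(prev, cur);
  }

  // backtrack interval boundaries
  std::vector<int> cl_sorted(n);
  int hi = n - 1;
  for (int m = k - 1; m >= 0; --m) {
    const int lo = (m == 0) ? 0 : (int)splits[m][hi];
    for (int i = lo; i <= hi; ++i) cl_sorted[i] = m + 1;
    hi = lo - 1;
  }

  NumericVector centers(k);
  IntegerVector sizes(k);
  for (int i = 0; i < n; ++i) {
    centers[cl_sorted[i] - 1] += xs[i];
    sizes[cl_sorted[i] - 1] += 1;
  }
  for (int m = 0; m < k; ++m) centers[m] /= sizes[m];

  IntegerVector cluster(n);
  for (int i = 0; i < n; ++i) cluster[ord[i]] = cl_sorted[i];

  double wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = x[i] - centers[cluster[i] - 1];
    wcss += d * d;
  }

  return List::create(_["cluster"] = cluster, _["centers"] = centers,
                      _["size"] = sizes, _["wcss"] = wcss);
}
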
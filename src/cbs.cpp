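#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Two-sample |t| over circular arcs (i, j] of an ordered series.
// Boundaries i < j split the series into inside = x[i..j-1] (0-based) and
// outside = the rest; the pooled within-group variance is floored at a small
// multiple of the series' total variance so that noiseless data rank arcs by
// effect size instead of collapsing every nonzero contrast to +Inf.

struct ArcScan {
  int i, j;
  double t;
};

static ArcScan scan_max_t(const std::vector<double>& x, int min_width,
                          int stride, int i_lo, int i_hi, int j_lo, int j_hi) {
  const int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
  const double total_mean = S[n] / n;
  const double total_var = Q[n] / n - total_mean * total_mean;
  const double floor_var = (total_var > 0 ? total_var : 1.0) * 1e-10;
  const int df = n - 2;

  ArcScan best{-1, -1, -1.0};
  if (df <= 0) return best;
  for (int i = std::max(0, i_lo); i <= std::min(n - 1, i_hi); i += stride) {
    for (int j = std::max(i + 1, j_lo); j <= std::min(n, j_hi); j += stride) {
      const int n1 = j - i;
      const int n2 = n - n1;
      if (n1 < min_width || n2 < min_width) continue;
      const double sum1 = S[j] - S[i];
      const double sum2 = S[n] - sum1;
      const double m1 = sum1 / n1, m2 = sum2 / n2;
      double ssw = Q[n] - (sum1 * sum1 / n1 + sum2 * sum2 / n2);
      if (ssw < 0) ssw = 0;
      double pooled = ssw / df;
      if (pooled < floor_var) pooled = floor_var;
      const double t = std::fabs(m1 - m2) /
        std::sqrt(pooled * (1.0 / n1 + 1.0 / n2));
      if (t > best.t) { best.i = i; best.j = j; best.t = t; }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cbs_max_t")]]
List cbs_max_t(NumericVector x, int min_width, int stride = 1,
               int i_lo = 0, int i_hi = -1, int j_lo = 1, int j_hi = -1) {
  const int n = x.size();
  if (i_hi < 0) i_hi = n - 1;
  if (j_hi < 0) j_hi = n;
  std::vector<double> v(x.begin(), x.end());
  ArcScan best = scan_max_t(v, min_width, stride, i_lo, i_hi, j_lo, j_hi);
  return List::create(_["i"] = best.i, _["j"] = best.j, _["t"] = best.t);
}

// Permutation p-value for the observed max |t|. Permutations stop early as
// soon as the exceedance count can no longer come in at or below alpha.
// [[Rcpp::export(name = ".cbs_perm_p")]]
double cbs_perm_p(NumericVector x, double t_obs, int min_width, int n_perm,
                  double alpha, int seed, int stride = 1) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::mt19937 rng((unsigned)seed);
  int exceed = 0;
  const int limit = (int)std::floor(alpha * n_perm);
  int done = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      std::uniform_int_distribution<int> d(0, k);
      std::swap(v[k], v[d(rng)]);
    }
    ArcScan b = scan_max_t(v, min_width, stride, 0, n - 1, 1, n);
    if (b.t >= t_obs - 1e-12) ++exceed;
    ++done;
    if (exceed > limit) break;
  }
  return (double)exceed / (double)(exceed > limit ? n_perm : done);
}
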
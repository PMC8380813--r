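#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation core: scan every circular arc of a segment
// for the maximal two-sample t-statistic (arc vs complement), and the
// permutation reference distribution of that maximum.
//
// Arcs are parameterized by 0 <= i < j <= m: the arc is x[(i+1)..j]
// (1-based). Because |t| is invariant under swapping arc and complement,
// scanning non-wrapping arcs covers all circular arcs (the standard
// sequence-doubling argument collapses to this for the max statistic).
// Constraints: arc and complement each hold >= min_bins bins, and any
// linear piece left by an interior cut also holds >= min_bins, so the
// resulting segments always satisfy the minimum-size invariant.
// Pooled variance is floored at 1e-9 so perfect (noiseless) steps get a
// large finite t. Ties are broken toward the smallest i, then smallest j.

static const double S2_FLOOR = 1e-9;

// Scan all valid arcs of x; fills best |t| and its (i, j). If early_exit is
// positive, returns as soon as some arc exceeds it (used in permutations,
// where only the comparison with the observed maximum matters).
static void scan_max(const std::vector<double>& x, int min_bins,
                     double early_exit, double& best_t, int& best_i,
                     int& best_j) {
  const int m = (int)x.size();
  best_t = -1.0;
  best_i = -1;
  best_j = -1;
  if (m < 2 * min_bins) return;
  std::vector<double> S(m + 1, 0.0), Q(m + 1, 0.0);
  for (int k = 0; k < m; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
  const double tot = S[m], totq = Q[m];
  const double denom_df = (m > 2) ? (double)(m - 2) : 1.0;
  for (int i = 0; i + min_bins <= m; ++i) {
    if (i > 0 && i < min_bins) continue;          // left piece too small
    for (int j = i + min_bins; j <= m; ++j) {
      const int k = j - i, nc = m - k;
      if (nc < min_bins) break;                   // shrinks as j grows
      if (i > 0 && j == m) continue;  // duplicate of edge arc (0, i)
      if (j < m && m - j < min_bins) continue;    // right piece too small
      const double sa = S[j] - S[i], sc = tot - sa;
      const double ma = sa / k, mc = sc / nc;
      const double qa = Q[j] - Q[i];
      double s2 = ((qa - k * ma * ma) + ((totq - qa) - nc * mc * mc)) /
                  denom_df;
      if (s2 < S2_FLOOR) s2 = S2_FLOOR;
      const double t = std::fabs((ma - mc) /
                                 std::sqrt(s2 * (1.0 / k + 1.0 / nc)));
      if (t > best_t) {
        best_t = t;
        best_i = i;
        best_j = j;
        if (early_exit > 0.0 && t > early_exit) return;
      }
    }
  }
}

// [[Rcpp::export]]
List cbs_best_arc_cpp(NumericVector x, int min_bins) {
  std::vector<double> v(x.begin(), x.end());
  double bt;
  int bi, bj;
  scan_max(v, min_bins, -1.0, bt, bi, bj);
  return List::create(_["t"] = bt, _["i"] = bi, _["j"] = bj,
                      _["valid"] = (bi >= 0));
}

// Permutation p-value for the observed max |t|: p = (1 + #{perm max > t_obs})
// / (1 + nperm), strictly greater so that a permutation reproducing a
// perfect step exactly does not count against it. Stops early once enough
// exceedances guarantee p > alpha (the returned value is then a valid lower
// bound that still exceeds alpha). Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
double cbs_perm_pvalue_cpp(NumericVector x, int min_bins, double t_obs,
                           int nperm, double alpha) {
  std::vector<double> v(x.begin(), x.end());
  const int m = (int)v.size();
  int exceed = 0;
  const int stop_at = (int)std::floor(alpha * (nperm + 1));
  for (int p = 0; p < nperm; ++p) {
    for (int k = m - 1; k > 0; --k) {  // Fisher-Yates
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(v[k], v[idx]);
    }
    double bt;
    int bi, bj;
    scan_max(v, min_bins, t_obs, bt, bi, bj);
    if (bt > t_obs) {
      ++exceed;
      if (stop_at > 0 && exceed >= stop_at)
        return (double)(1 + exceed) / (double)(1 + nperm);
    }
  }
  return (double)(1 + exceed) / (double)(1 + nperm);
}
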
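#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Cumulative-error threshold sweep.  Mirrors the documented contract of
// optimize_threshold(): evaluate every admissible cut (midpoints between
// consecutive distinct scores plus below/above sentinels) for both
// comparison directions; minimize the misclassification count; break ties
// by widest gap, then smallest cut value, then score_greater.
// [[Rcpp::export]]
List cpp_threshold_sweep(NumericVector scores, LogicalVector ypos) {
  const int n = scores.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return scores[a] < scores[b]; });

  // finite surrogate axis for cut placement (errors use rank positions)
  std::vector<double> sf(n);
  double lo = 0.0, hi = 0.0;
  bool any_fin = false;
  for (int i = 0; i < n; ++i) {
    double v = scores[ord[i]];
    if (std::isfinite(v)) {
      if (!any_fin) { lo = hi = v; any_fin = true; }
      else { lo = std::min(lo, v); hi = std::max(hi, v); }
    }
  }
  for (int i = 0; i < n; ++i) {
    double v = scores[ord[i]];
    if (v == R_PosInf) v = hi + 2.0;
    else if (v == R_NegInf) v = lo - 2.0;
    sf[i] = v;
  }

  std::vector<int> cp(n + 1, 0), cn(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    cp[i + 1] = cp[i] + (ypos[ord[i]] ? 1 : 0);
    cn[i + 1] = cn[i] + (ypos[ord[i]] ? 0 : 1);
  }
  const int npos = cp[n], nneg = cn[n];

  int best_err = n + 1;
  double best_gap = -1.0, best_cut = 0.0;
  bool best_greater = true;
  bool have = false;

  // boundary j separates the j lowest scores from the rest (j = 0..n)
  for (int j = 0; j <= n; ++j) {
    if (j > 0 && j < n && !(sf[j] > sf[j - 1])) continue;  // inside a tie run
    const bool sentinel = (j == 0 || j == n);
    const double gap = sentinel ? R_PosInf : sf[j] - sf[j - 1];
    const double cut = (j == 0) ? sf[0] - 1.0
                       : (j == n) ? sf[n - 1] + 1.0
                       : (sf[j - 1] + sf[j]) / 2.0;
    const int err_g = cp[j] + (nneg - cn[j]);   // positive iff score > cut
    const int err_l = cn[j] + (npos - cp[j]);   // positive iff score < cut
    for (int d = 0; d < 2; ++d) {
      const bool greater = (d == 0);
      const int err = greater ? err_g : err_l;
      bool better = false;
      if (!have || err < best_err) better = true;
      else if (err == best_err) {
        if (gap > best_gap) better = true;
        else if (gap == best_gap) {
          if (cut < best_cut) better = true;
          else if (cut == best_cut && greater && !best_greater) better = true;
        }
      }
      if (better) {
        have = true;
        best_err = err; best_gap = gap; best_cut = cut; best_greater = greater;
      }
    }
  }

  return List::create(_["cut"] = best_cut,
                      _["dir"] = best_greater ? "score_greater" : "score_less",
                      _["err"] = best_err);
}
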
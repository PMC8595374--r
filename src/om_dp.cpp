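#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch-style global alignment cost over a precomputed
// position-cost matrix. cost(i, j) is the (possibly expected)
// substitution cost of aligning position i of the first sequence with
// position j of the second; insertions and deletions cost `indel` each.
// Ties are broken in fixed order (diagonal, up, left), which affects
// scripts but not the returned distance.
// [[Rcpp::export(name = ".om_dp")]]
double om_dp(NumericMatrix cost, double indel) {
  int n = cost.nrow(), m = cost.ncol();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + cost(i - 1, j - 1);
      double u = prev[j] + indel;
      double l = cur[j - 1] + indel;
      double best = d;
      if (u < best) best = u;
      if (l < best) best = l;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
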
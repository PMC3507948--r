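#include <Rcpp.h>
using namespace Rcpp;

// Permutation engine for the type-II site statistic.
//
// codes:  members x columns integer matrix; 0 = gap, 1..21 = residue code in
//         alphabetical order (so an ascending scan breaks modal ties toward
//         the alphabetically smallest residue).
// groupA: assignments x nA matrix of 1-based member row indices forming
//         group A under each (re)partition; the remaining rows form group B.
// t_obs:  per-column observed statistic (NA marks columns to skip).
//
// Returns, per column, the number of assignments whose statistic
// T* = freqA * freqB * [consensusA != consensusB] is >= t_obs (within 1e-12).
// [[Rcpp::export]]
IntegerVector type2_perm_counts(const IntegerMatrix& codes,
                                const IntegerMatrix& groupA,
                                const NumericVector& t_obs) {
  const int n_mem = codes.nrow();
  const int n_col = codes.ncol();
  const int n_assign = groupA.nrow();
  const int nA = groupA.ncol();
  if (t_obs.size() != n_col) stop("t_obs length must equal column count");

  // total residue counts per column
  std::vector<int> tot(22 * n_col, 0), totN(n_col, 0);
  for (int c = 0; c < n_col; ++c) {
    for (int m = 0; m < n_mem; ++m) {
      int v = codes(m, c);
      if (v > 0) { tot[22 * c + v]++; totN[c]++; }
    }
  }

  IntegerVector counts(n_col, 0);
  std::vector<int> cntA(22);
  for (int a = 0; a < n_assign; ++a) {
    for (int c = 0; c < n_col; ++c) {
      double to = t_obs[c];
      if (ISNAN(to)) continue;
      std::fill(cntA.begin(), cntA.end(), 0);
      int nAc = 0;
      for (int k = 0; k < nA; ++k) {
        int v = codes(groupA(a, k) - 1, c);
        if (v > 0) { cntA[v]++; nAc++; }
      }
      int nBc = totN[c] - nAc;
      double T = 0.0;
      if (nAc > 0 && nBc > 0) {
        int maxA = 0, argA = 0, maxB = 0, argB = 0;
        for (int v = 1; v <= 21; ++v) {
          if (cntA[v] > maxA) { maxA = cntA[v]; argA = v; }
          int b = tot[22 * c + v] - cntA[v];
          if (b > maxB) { maxB = b; argB = v; }
        }
        if (argA != argB) {
          T = (double)maxA / nAc * (double)maxB / nBc;
        }
      }
      if (T >= to - 1e-12) counts[c]++;
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
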
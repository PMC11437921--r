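#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Tie-aware Mann-Whitney AUC for every row of X over a set of bootstrap
// resamples. idx is an (npos + nneg) x n_boot matrix of 1-based column
// indices into X; within each column the first npos entries are the
// positive-class draws. Ties contribute one half via midrank averaging.
// [[Rcpp::export]]
NumericMatrix cpp_auc_boot(NumericMatrix X, IntegerMatrix idx, int npos) {
  const int P = X.nrow();
  const int B = idx.ncol();
  const int m = idx.nrow();
  const int nneg = m - npos;
  if (npos < 1 || nneg < 1) stop("both classes must be non-empty");
  NumericMatrix out(P, B);
  std::vector<double> v(m);
  std::vector<int> ord(m), take(m);
  // transpose once so each protein's values are contiguous
  const int n = X.ncol();
  std::vector<double> tX(static_cast<size_t>(n) * P);
  for (int p = 0; p < P; ++p)
    for (int j = 0; j < n; ++j)
      tX[static_cast<size_t>(p) * n + j] = X(p, j);
  const double offset = npos * (npos + 1.0) / 2.0;
  const double denom = static_cast<double>(npos) * nneg;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < m; ++i) take[i] = idx(i, b) - 1;
    for (int p = 0; p < P; ++p) {
      const double *col = &tX[static_cast<size_t>(p) * n];
      for (int i = 0; i < m; ++i) v[i] = col[take[i]];
      for (int i = 0; i < m; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int c) { return v[a] < v[c]; });
      double rsum = 0.0;
      int i = 0;
      while (i < m) {
        int j = i;
        while (j + 1 < m && v[ord[j + 1]] == v[ord[i]]) ++j;
        const double midrank = (i + j) / 2.0 + 1.0;
        for (int k = i; k <= j; ++k)
          if (ord[k] < npos) rsum += midrank;
        i = j + 1;
      }
      out(p, b) = (rsum - offset) / denom;
    }
  }
  return out;
}
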
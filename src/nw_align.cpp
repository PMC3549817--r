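#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty over a
// precomputed column-score matrix. S(i, j) is the score of aligning column
// i+1 of the first profile with column j+1 of the second. Traceback ties are
// broken diagonal > up > left, so the reported alignment is deterministic.
//
// Returns the optimal score and the aligned column indices of both inputs
// (0 marks a gap column).
// [[Rcpp::export]]
List nw_align_cpp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int i = 1; i <= n; ++i) { D(i, 0) = i * gap; T(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { D(0, j) = j * gap; T(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double d = D(i - 1, j - 1) + S(i - 1, j - 1);
      const double u = D(i - 1, j) + gap;
      const double l = D(i, j - 1) + gap;
      if (d >= u && d >= l)      { D(i, j) = d; T(i, j) = 0; }
      else if (u >= l)           { D(i, j) = u; T(i, j) = 1; }
      else                       { D(i, j) = l; T(i, j) = 2; }
    }
  }
  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int t = (i == 0) ? 2 : (j == 0) ? 1 : T(i, j);
    if (t == 0)      { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (t == 1) { ai.push_back(i); bi.push_back(0); --i; }
    else             { ai.push_back(0); bi.push_back(j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = D(n, m),
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
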
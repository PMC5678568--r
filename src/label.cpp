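#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling under 4- or 8-connectivity (flood fill).
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix m, int connectivity) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!m(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int k = stack.back();
        stack.pop_back();
        int cr = k % nr, cc = k / nr;
        for (int d = 0; d < nnb; ++d) {
          int r2 = cr + dr8[d], c2 = cc + dc8[d];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (m(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(c2 * nr + r2);
          }
        }
      }
    }
  }
  return lab;
}
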
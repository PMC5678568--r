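#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Zhang-Suen morphological thinning to a 1-pixel-wide, 8-connected skeleton.
// Homotopy-preserving; endpoints are never removed, so 1-px-wide open curves
// are fixed points of the operator.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix im = clone(m);
  auto P = [&](int r, int c) -> int {
    return (r < 0 || c < 0 || r >= nr || c >= nc) ? 0 : (im(r, c) != 0);
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!im(r, c)) continue;
          int p2 = P(r - 1, c), p3 = P(r - 1, c + 1), p4 = P(r, c + 1),
              p5 = P(r + 1, c + 1), p6 = P(r + 1, c), p7 = P(r + 1, c - 1),
              p8 = P(r, c - 1), p9 = P(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (seq[i] == 0 && seq[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < del.size(); ++i) im(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return im;
}
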
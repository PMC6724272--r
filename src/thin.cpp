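#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a 0/1 integer matrix (expects a 1-px zero border).
// Neighbours P2..P9 clockwise from north; a pixel is deletable when it has
// 2..6 foreground neighbours, exactly one 0->1 transition around it, and
// the directional products of the current subpass vanish.
// [[Rcpp::export(name = ".zs_thin_cpp")]]
IntegerMatrix zs_thin_cpp(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(clone(m));
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (out(i, j) != 1) continue;
          int p2 = out(i - 1, j),     p3 = out(i - 1, j + 1);
          int p4 = out(i, j + 1),     p5 = out(i + 1, j + 1);
          int p6 = out(i + 1, j),     p7 = out(i + 1, j - 1);
          int p8 = out(i, j - 1),     p9 = out(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(i + j * nr);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) out[del[k]] = 0;
      }
    }
  }
  return out;
}
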
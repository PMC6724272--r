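#include <Rcpp.h>
#include <cmath>
#include <deque>
using namespace Rcpp;

// Moving min (or max) of width 2*w+1 along a vector, outside treated as
// absent (shrinking window at the ends). Van Herk-style via monotonic deque.
static void run_minmax(const double* x, int n, int w, bool take_max,
                       double* out) {
  std::deque<int> q;
  for (int i = 0; i < n + w; ++i) {
    if (i < n) {
      while (!q.empty() &&
             (take_max ? x[q.back()] <= x[i] : x[q.back()] >= x[i]))
        q.pop_back();
      q.push_back(i);
    }
    int j = i - w;              // output index whose window ends at i
    if (j >= 0) {
      while (q.front() < j - w) q.pop_front();
      out[j] = x[q.front()];
    }
  }
}

// Grayscale min/max filter over a disc of radius r: horizontal moving
// min/max per required half-width, then a vertical combine across row
// offsets. Border windows shrink (outside pixels are ignored).
// [[Rcpp::export(name = ".disc_minmax_cpp")]]
NumericMatrix disc_minmax_cpp(NumericMatrix m, int r, bool take_max) {
  int nr = m.nrow(), nc = m.ncol();
  // half-width of the disc at each row offset
  std::vector<int> hw(r + 1);
  for (int dy = 0; dy <= r; ++dy)
    hw[dy] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
  // horizontal pass for each distinct width, indexed by half-width
  std::vector<int> widths(hw.begin(), hw.end());
  std::sort(widths.begin(), widths.end());
  widths.erase(std::unique(widths.begin(), widths.end()), widths.end());
  // store horizontal results per distinct width
  std::map<int, NumericMatrix> H;
  std::vector<double> rowbuf(nc), outbuf(nc);
  for (size_t k = 0; k < widths.size(); ++k) {
    int w = widths[k];
    NumericMatrix h(nr, nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowbuf[j] = m(i, j);
      run_minmax(rowbuf.data(), nc, w, take_max, outbuf.data());
      for (int j = 0; j < nc; ++j) h(i, j) = outbuf[j];
    }
    H.insert(std::make_pair(w, h));
  }
  NumericMatrix out(nr, nc);
  double init = take_max ? R_NegInf : R_PosInf;
  std::fill(out.begin(), out.end(), init);
  for (int dy = -r; dy <= r; ++dy) {
    NumericMatrix& h = H[hw[std::abs(dy)]];
    for (int j = 0; j < nc; ++j) {
      int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
      for (int i = i0; i < i1; ++i) {
        double v = h(i + dy, j);
        if (take_max ? v > out(i, j) : v < out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// Windowed sum over a (2n+1) box, outside treated as zero.
// [[Rcpp::export(name = ".box_sum_cpp")]]
NumericMatrix box_sum_cpp(NumericMatrix m, int n) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix h(nr, nc);
  // horizontal prefix sums
  std::vector<double> pref(nc + 1);
  for (int i = 0; i < nr; ++i) {
    pref[0] = 0;
    for (int j = 0; j < nc; ++j) pref[j + 1] = pref[j] + m(i, j);
    for (int j = 0; j < nc; ++j) {
      int a = std::max(0, j - n), b = std::min(nc - 1, j + n);
      h(i, j) = pref[b + 1] - pref[a];
    }
  }
  NumericMatrix out(nr, nc);
  std::vector<double> prefv(nr + 1);
  for (int j = 0; j < nc; ++j) {
    prefv[0] = 0;
    for (int i = 0; i < nr; ++i) prefv[i + 1] = prefv[i] + h(i, j);
    for (int i = 0; i < nr; ++i) {
      int a = std::max(0, i - n), b = std::min(nr - 1, i + n);
      out(i, j) = prefv[b + 1] - prefv[a];
    }
  }
  return out;
}

// Sums of m and m^2 over a disc of radius r (outside treated as zero),
// via per-row horizontal prefix sums combined across row offsets.
// [[Rcpp::export(name = ".disc_sum2_cpp")]]
List disc_sum2_cpp(NumericMatrix m, int r) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix pref(nr, nc + 1), pref2(nr, nc + 1);
  for (int i = 0; i < nr; ++i) {
    pref(i, 0) = 0; pref2(i, 0) = 0;
    for (int j = 0; j < nc; ++j) {
      pref(i, j + 1) = pref(i, j) + m(i, j);
      pref2(i, j + 1) = pref2(i, j) + m(i, j) * m(i, j);
    }
  }
  std::vector<int> hw(r + 1);
  for (int dy = 0; dy <= r; ++dy)
    hw[dy] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
  NumericMatrix out(nr, nc), out2(nr, nc);
  for (int dy = -r; dy <= r; ++dy) {
    int w = hw[std::abs(dy)];
    int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
    for (int j = 0; j < nc; ++j) {
      int a = std::max(0, j - w), b = std::min(nc - 1, j + w);
      for (int i = i0; i < i1; ++i) {
        out(i, j) += pref(i + dy, b + 1) - pref(i + dy, a);
        out2(i, j) += pref2(i + dy, b + 1) - pref2(i + dy, a);
      }
    }
  }
  return List::create(out, out2);
}
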
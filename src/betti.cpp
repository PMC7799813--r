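#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Digital topology convention used throughout: foreground 8-connected,
// background 4-connected (the standard pairing that avoids connectivity
// paradoxes on the square lattice). A "hole" (b1) is a background
// component that does not touch the window border.

namespace {

// Flood fill over an integer buffer (0 = background of the fill, 1 = fillable).
// Marks visited cells with `label` in lab. Returns true if the component
// touches the border. nr, nc: buffer dims (column-major, R layout).
bool flood(const std::vector<unsigned char>& img, std::vector<int>& lab,
           int nr, int nc, int start, int label, bool conn8,
           std::vector<int>& stack) {
  bool border = false;
  stack.clear();
  stack.push_back(start);
  lab[start] = label;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx % nr, c = idx / nr;
    if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) border = true;
    const int dr4[4] = {1, -1, 0, 0};
    const int dc4[4] = {0, 0, 1, -1};
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr4[d], cc = c + dc4[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      if (img[j] && lab[j] == 0) { lab[j] = label; stack.push_back(j); }
    }
    if (conn8) {
      const int dr8[4] = {1, 1, -1, -1};
      const int dc8[4] = {1, -1, 1, -1};
      for (int d = 0; d < 4; ++d) {
        int rr = r + dr8[d], cc = c + dc8[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = rr + cc * nr;
        if (img[j] && lab[j] == 0) { lab[j] = label; stack.push_back(j); }
      }
    }
  }
  return border;
}

// Betti pair of a binary window given as a flat buffer.
inline void betti_core(const std::vector<unsigned char>& fg, int nr, int nc,
                       int& b0, int& b1,
                       std::vector<int>& lab, std::vector<int>& stack,
                       std::vector<unsigned char>& bg) {
  int n = nr * nc;
  std::fill(lab.begin(), lab.begin() + n, 0);
  b0 = 0;
  for (int i = 0; i < n; ++i)
    if (fg[i] && lab[i] == 0) flood(fg, lab, nr, nc, i, ++b0, true, stack);
  // holes: 4-connected background components not touching the border
  for (int i = 0; i < n; ++i) bg[i] = fg[i] ? 0 : 1;
  std::fill(lab.begin(), lab.begin() + n, 0);
  b1 = 0;
  int lbl = 0;
  for (int i = 0; i < n; ++i)
    if (bg[i] && lab[i] == 0)
      if (!flood(bg, lab, nr, nc, i, ++lbl, false, stack)) ++b1;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_betti(LogicalMatrix w) {
  int nr = w.nrow(), nc = w.ncol(), n = nr * nc;
  std::vector<unsigned char> fg(n), bg(n);
  for (int i = 0; i < n; ++i) fg[i] = w[i] ? 1 : 0;
  std::vector<int> lab(n), stack;
  int b0, b1;
  betti_core(fg, nr, nc, b0, b1, lab, stack, bg);
  return IntegerVector::create(Named("b0") = b0, Named("b1") = b1);
}

// Sliding-window Betti maps for every threshold in `thresholds`
// (binarization: pixel >= t is foreground). Windows are k x k, advance by
// stride s, and only fully contained windows are evaluated. Returns a list
// with integer arrays b0 and b1 of dim (n_row_windows, n_col_windows, n_thr).
// [[Rcpp::export]]
List cpp_bn_maps(IntegerMatrix img, int k, int s, IntegerVector thresholds) {
  int nr = img.nrow(), nc = img.ncol();
  if (nr < k || nc < k) stop("image smaller than kernel");
  int mr = (nr - k) / s + 1, mc = (nc - k) / s + 1;
  int nt = thresholds.size();
  IntegerVector b0_out(mr * mc * nt), b1_out(mr * mc * nt);
  std::vector<unsigned char> bin(nr * nc), fg(k * k), bgbuf(k * k);
  std::vector<int> lab(k * k), stack;
  for (int ti = 0; ti < nt; ++ti) {
    int t = thresholds[ti];
    for (int i = 0; i < nr * nc; ++i) bin[i] = img[i] >= t ? 1 : 0;
    for (int wc = 0; wc < mc; ++wc) {
      int c0 = wc * s;
      for (int wr = 0; wr < mr; ++wr) {
        int r0 = wr * s;
        for (int jj = 0; jj < k; ++jj)
          for (int ii = 0; ii < k; ++ii)
            fg[ii + jj * k] = bin[(r0 + ii) + (c0 + jj) * nr];
        int b0, b1;
        betti_core(fg, k, k, b0, b1, lab, stack, bgbuf);
        int idx = wr + wc * mr + ti * mr * mc;
        b0_out[idx] = b0;
        b1_out[idx] = b1;
      }
    }
  }
  b0_out.attr("dim") = IntegerVector::create(mr, mc, nt);
  b1_out.attr("dim") = IntegerVector::create(mr, mc, nt);
  return List::create(Named("b0") = b0_out, Named("b1") = b1_out);
}
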
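#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Texture-matrix builders. All take a discretized map `lev` with gray levels
// 1..G inside the ROI and 0 outside (0 never pairs, never runs, never zones).
// Matrix layout is column-major (R).

// Direction set 0/45/90/135 degrees in (row, col) offsets. 0 degrees is the
// horizontal image direction (constant row).
static const int DR[4] = {0, -1, -1, -1};
static const int DC[4] = {1,  1,  0, -1};

// Co-occurrence counts at distance 1, one G x G slab per direction,
// symmetric (each ordered pair counted both ways).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerMatrix lev, int G) {
  int nr = lev.nrow(), nc = lev.ncol();
  NumericVector out((R_xlen_t)G * G * 4);
  for (int d = 0; d < 4; ++d) {
    R_xlen_t off = (R_xlen_t)d * G * G;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int a = lev(r, c);
        if (a == 0) continue;
        int rr = r + DR[d], cc = c + DC[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int b = lev(rr, cc);
        if (b == 0) continue;
        out[off + (a - 1) + (R_xlen_t)(b - 1) * G] += 1.0;
        out[off + (b - 1) + (R_xlen_t)(a - 1) * G] += 1.0;
      }
  }
  out.attr("dim") = IntegerVector::create(G, G, 4);
  return out;
}

// Run-length counts merged (summed) over the directions in `dirs`
// (0-based indices into the 0/45/90/135 set): G x Lmax, where
// Lmax = max(nr, nc). Runs are maximal same-level segments inside the ROI;
// an out-of-ROI pixel breaks a run.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerMatrix lev, int G, IntegerVector dirs) {
  int nr = lev.nrow(), nc = lev.ncol();
  int lmax = std::max(nr, nc);
  NumericMatrix M(G, lmax);
  for (int di = 0; di < dirs.size(); ++di) {
    int d = dirs[di];
    int dr = -DR[d], dc = -DC[d]; // walk forward along the direction
    // starting points: cells with no same-direction predecessor in-grid
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int pr = r - dr, pc = c - dc;
        bool is_start = pr < 0 || pr >= nr || pc < 0 || pc >= nc;
        if (!is_start) continue;
        int rr = r, cc = c;
        int cur = 0, len = 0;
        while (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
          int v = lev(rr, cc);
          if (v == cur && v != 0) {
            ++len;
          } else {
            if (cur != 0) M(cur - 1, len - 1) += 1.0;
            cur = v;
            len = v != 0 ? 1 : 0;
          }
          rr += dr; cc += dc;
        }
        if (cur != 0) M(cur - 1, len - 1) += 1.0;
      }
  }
  return M;
}

// Size zones: 8-connected components of equal nonzero level. Returns a
// two-column integer matrix (level, size), one row per zone, in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_zone_sizes(IntegerMatrix lev) {
  int nr = lev.nrow(), nc = lev.ncol();
  std::vector<int> seen((size_t)nr * nc, 0);
  std::vector<int> zl, zs, stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i0 = r + c * nr;
      int v = lev[i0];
      if (v == 0 || seen[i0]) continue;
      int size = 0;
      stack.clear();
      stack.push_back(i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        ++size;
        int rr = idx % nr, cc = idx / nr;
        for (int dc2 = -1; dc2 <= 1; ++dc2)
          for (int dr2 = -1; dr2 <= 1; ++dr2) {
            if (dr2 == 0 && dc2 == 0) continue;
            int r2 = rr + dr2, c2 = cc + dc2;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int j = r2 + c2 * nr;
            if (!seen[j] && lev[j] == v) { seen[j] = 1; stack.push_back(j); }
          }
      }
      zl.push_back(v);
      zs.push_back(size);
    }
  IntegerMatrix Z(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { Z(i, 0) = zl[i]; Z(i, 1) = zs[i]; }
  colnames(Z) = CharacterVector::create("level", "size");
  return Z;
}

// Neighbourhood gray-tone difference accumulators: for each level i, n[i] =
// number of in-ROI pixels of level i that have at least one in-ROI
// 8-neighbour, s[i] = sum over those pixels of |i - mean(in-ROI neighbours)|.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerMatrix lev, int G) {
  int nr = lev.nrow(), nc = lev.ncol();
  IntegerVector n(G);
  NumericVector s(G);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int v = lev(r, c);
      if (v == 0) continue;
      double sum = 0.0;
      int cnt = 0;
      for (int dc2 = -1; dc2 <= 1; ++dc2)
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          if (dr2 == 0 && dc2 == 0) continue;
          int r2 = r + dr2, c2 = c + dc2;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int w = lev(r2, c2);
          if (w == 0) continue;
          sum += w;
          ++cnt;
        }
      if (cnt == 0) continue;
      n[v - 1] += 1;
      s[v - 1] += std::abs((double)v - sum / cnt);
    }
  return List::create(Named("n") = n, Named("s") = s);
}
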
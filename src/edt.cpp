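#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Euclidean distance transform of a 3-D site set, separable
// lower-envelope algorithm (Felzenszwalb & Huttenlocher) run per axis with
// physical spacing. Input: logical array flattened column-major with dims
// (d1, d2, d3); TRUE marks sites. Output: squared distance (mm^2) from each
// voxel to the nearest site. Callers must ensure at least one site; with no
// sites every output is ~BIG (not a usable distance).

namespace {
const double BIG = 1e20; // finite stand-in for +infinity; keeps envelope math exact

void dt1d(const std::vector<double>& f, std::vector<double>& out, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0 and new parabola dominates everywhere
      v[0] = q;
      z[0] = -BIG;
      z[1] = BIG;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double d = xq - v[k] * h;
    out[q] = d * d + f[v[k]];
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_sq_edt3d(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = sites[i] ? 0.0 : BIG;
  std::vector<double> f(std::max(d1, std::max(d2, d3)));
  std::vector<double> out(f.size());
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y) {
      R_xlen_t base = (R_xlen_t)y * d1 + (R_xlen_t)z * d1 * d2;
      for (int x = 0; x < d1; ++x) f[x] = D[base + x];
      dt1d(f, out, d1, spacing[0]);
      for (int x = 0; x < d1; ++x) D[base + x] = out[x];
    }
  for (int z = 0; z < d3; ++z)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)z * d1 * d2;
      for (int y = 0; y < d2; ++y) f[y] = D[base + (R_xlen_t)y * d1];
      dt1d(f, out, d2, spacing[1]);
      for (int y = 0; y < d2; ++y) D[base + (R_xlen_t)y * d1] = out[y];
    }
  for (int y = 0; y < d2; ++y)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)y * d1;
      for (int z = 0; z < d3; ++z) f[z] = D[base + (R_xlen_t)z * d1 * d2];
      dt1d(f, out, d3, spacing[2]);
      for (int z = 0; z < d3; ++z) D[base + (R_xlen_t)z * d1 * d2] = out[z];
    }
  D.attr("dim") = dims;
  return D;
}
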
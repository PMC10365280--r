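#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static int build_offsets(int connectivity, int off[26][3]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off[k][0] = dx; off[k][1] = dy; off[k][2] = dz; ++k;
      }
  return k;
}

// Label connected components of a binary 3D mask.
// Returns integer labels 1..K in discovery (scan) order, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  int off[26][3];
  const int noff = build_offsets(connectivity, off);
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++cur;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int zi = (int)(v / nxy);
      int rem = (int)(v - (R_xlen_t)zi * nxy);
      int yi = rem / nx, xi = rem % nx;
      for (int k = 0; k < noff; ++k) {
        int xj = xi + off[k][0], yj = yi + off[k][1], zj = zi + off[k][2];
        if (xj < 0 || yj < 0 || zj < 0 || xj >= nx || yj >= ny || zj >= nz)
          continue;
        R_xlen_t w = xj + nx * (R_xlen_t)yj + nxy * zj;
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}
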
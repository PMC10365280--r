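#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// union-find with path halving
static inline int uf_find(std::vector<int> &parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

static int tfce_offsets(int connectivity, int off[26][3]) {
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

// Threshold-free cluster enhancement of a non-negative statistic map.
// TFCE(v) = sum over thresholds h = dh, 2dh, ..., nsteps*dh of
//           extent(v,h)^E * h^H * dh, where extent(v,h) is the size of
//           the connected component containing v among voxels >= h.
// Voxels are swept once from high to low threshold with an incremental
// union-find, so the cost is O(nsteps * n_active * alpha).
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int nsteps,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dims");
  if (dh <= 0 || nsteps < 1) stop("dh must be > 0 and nsteps >= 1");
  int off[26][3];
  const int noff = tfce_offsets(connectivity, off);

  std::vector<int> active;
  active.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (stat[i] > 0) active.push_back((int)i);
  NumericVector out(n, 0.0);
  if (active.empty()) return out;

  // descending order of statistic value
  std::sort(active.begin(), active.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n, -1);
  std::vector<int> csize(n, 0);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  size_t ptr = 0;

  for (int s = nsteps; s >= 1; --s) {
    const double h = s * dh;
    // activate voxels with stat >= h and merge with active neighbours
    while (ptr < active.size() && stat[active[ptr]] >= h) {
      int v = active[ptr++];
      parent[v] = v;
      csize[v] = 1;
      int zi = (int)(v / nxy);
      int rem = (int)(v - (R_xlen_t)zi * nxy);
      int yi = rem / nx, xi = rem % nx;
      for (int k = 0; k < noff; ++k) {
        int xj = xi + off[k][0], yj = yi + off[k][1], zj = zi + off[k][2];
        if (xj < 0 || yj < 0 || zj < 0 || xj >= nx || yj >= ny || zj >= nz)
          continue;
        int w = (int)(xj + nx * (R_xlen_t)yj + nxy * zj);
        if (parent[w] < 0) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    if (ptr == 0) continue;
    const double hterm = std::pow(h, H) * dh;
    for (size_t a = 0; a < ptr; ++a) {
      int v = active[a];
      int r = uf_find(parent, v);
      out[v] += std::pow((double)csize[r], E) * hterm;
    }
  }
  return out;
}
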
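#include <Rcpp.h>
using namespace Rcpp;

// Keys cubic (Catmull-Rom, a = -0.5) kernel and derivative
static inline void keys_w(double f, double w[4], double dw[4]) {
  // weights for samples at offsets -1, 0, 1, 2 relative to floor
  const double a = -0.5;
  double t;
  t = 1 + f;  // distance for sample -1, in [1,2)
  w[0] = a * t * t * t - 5 * a * t * t + 8 * a * t - 4 * a;
  dw[0] = 3 * a * t * t - 10 * a * t + 8 * a;
  t = f;      // sample 0, in [0,1)
  w[1] = (a + 2) * t * t * t - (a + 3) * t * t + 1;
  dw[1] = 3 * (a + 2) * t * t - 2 * (a + 3) * t;
  t = 1 - f;  // sample 1, in (0,1]
  w[2] = (a + 2) * t * t * t - (a + 3) * t * t + 1;
  dw[2] = -(3 * (a + 2) * t * t - 2 * (a + 3) * t);
  t = 2 - f;  // sample 2, in (1,2]
  w[3] = a * t * t * t - 5 * a * t * t + 8 * a * t - 4 * a;
  dw[3] = -(3 * a * t * t - 10 * a * t + 8 * a);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Catmull-Rom cubic sampling of a 3D volume with the exact gradient of
// the interpolant w.r.t. continuous 0-based voxel coordinates.
// Returns N x 4: value, d/dx, d/dy, d/dz. Border voxels are clamped;
// points outside the grid return `fill` with zero gradient.
// [[Rcpp::export]]
NumericMatrix cpp_sample_cubic_grad(NumericVector src, IntegerVector dims,
                                    NumericMatrix coords, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericMatrix out(n, 4);
  const double *s = src.begin();
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    const double eps = 1e-6;
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < -eps || y < -eps || z < -eps ||
        x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) {
      out(p, 0) = fill;
      continue;
    }
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2;
    if (y0 > ny - 2) y0 = ny - 2;
    if (z0 > nz - 2) z0 = nz - 2;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double wx[4], dwx[4], wy[4], dwy[4], wz[4], dwz[4];
    keys_w(fx, wx, dwx);
    keys_w(fy, wy, dwy);
    keys_w(fz, wz, dwz);
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int kz = 0; kz < 4; ++kz) {
      int zi = clampi(z0 - 1 + kz, 0, nz - 1);
      for (int ky = 0; ky < 4; ++ky) {
        int yi = clampi(y0 - 1 + ky, 0, ny - 1);
        const double *row = s + nx * (R_xlen_t)yi + nxy * zi;
        double sx = 0, sdx = 0;
        for (int kx = 0; kx < 4; ++kx) {
          int xi = clampi(x0 - 1 + kx, 0, nx - 1);
          double c = row[xi];
          sx += wx[kx] * c;
          sdx += dwx[kx] * c;
        }
        double wyz = wy[ky] * wz[kz];
        v += wyz * sx;
        gx += wyz * sdx;
        gy += dwy[ky] * wz[kz] * sx;
        gz += wy[ky] * dwz[kz] * sx;
      }
    }
    out(p, 0) = v;
    out(p, 1) = gx;
    out(p, 2) = gy;
    out(p, 3) = gz;
  }
  return out;
}
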
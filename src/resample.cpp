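#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D volume at fractional 0-based voxel coordinates.
// coords: N x 3 matrix; points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector src, IntegerVector dims,
                                   NumericMatrix coords, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *s = src.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    const double eps = 1e-6;
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < -eps || y < -eps || z < -eps ||
        x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) {
      out[p] = fill;
      continue;
    }
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1);
    int y1 = std::min(y0 + 1, ny - 1);
    int z1 = std::min(z0 + 1, nz - 1);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    double c000 = s[x0 + nx * y0 + nxy * z0];
    double c100 = s[x1 + nx * y0 + nxy * z0];
    double c010 = s[x0 + nx * y1 + nxy * z0];
    double c110 = s[x1 + nx * y1 + nxy * z0];
    double c001 = s[x0 + nx * y0 + nxy * z1];
    double c101 = s[x1 + nx * y0 + nxy * z1];
    double c011 = s[x0 + nx * y1 + nxy * z1];
    double c111 = s[x1 + nx * y1 + nxy * z1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (masks, atlas labels).
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector src, IntegerVector dims,
                                 NumericMatrix coords, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *s = src.begin();
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
      out[p] = fill;
      continue;
    }
    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
    xi = std::max(0, std::min(xi, nx - 1));
    yi = std::max(0, std::min(yi, ny - 1));
    zi = std::max(0, std::min(zi, nz - 1));
    out[p] = s[xi + nx * yi + nxy * zi];
  }
  return out;
}
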
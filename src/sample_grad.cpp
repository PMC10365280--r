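#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling with the exact gradient of the interpolant with
// respect to the (continuous, 0-based) voxel coordinates. Returns an
// N x 4 matrix: value, d/dx, d/dy, d/dz. Outside the grid the value is
// `fill` and the gradient 0 (matching the flat out-of-field extension).
// [[Rcpp::export]]
NumericMatrix cpp_sample_trilinear_grad(NumericVector src, IntegerVector dims,
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
    if (x0 >= nx - 1) x0 = nx - 2;
    if (y0 >= ny - 1) y0 = ny - 2;
    if (z0 >= nz - 1) z0 = nz - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1);
    int y1 = std::min(y0 + 1, ny - 1);
    int z1 = std::min(z0 + 1, nz - 1);
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
    out(p, 0) = c0 * (1 - fz) + c1 * fz;
    // d/dx
    double dx00 = c100 - c000, dx10 = c110 - c010;
    double dx01 = c101 - c001, dx11 = c111 - c011;
    double dx0 = dx00 * (1 - fy) + dx10 * fy;
    double dx1 = dx01 * (1 - fy) + dx11 * fy;
    out(p, 1) = dx0 * (1 - fz) + dx1 * fz;
    // d/dy
    double dy0 = c10 - c00, dy1 = c11 - c01;
    out(p, 2) = dy0 * (1 - fz) + dy1 * fz;
    // d/dz
    out(p, 3) = c1 - c0;
  }
  return out;
}
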
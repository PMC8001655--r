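// Trilinear/bilinear sampling, affine and displacement-field warps,
// parallel-beam projections and 2D sub-pixel shifts.
// Convention: volumes are arma::cube indexed (z, y, x), 0-based here;
// R wrappers translate from 1-based indices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based (z, y, x); `fill` outside.
static inline double trilinear(const arma::cube& v, double z, double y,
                               double x, double fill) {
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  if (z < 0.0 || y < 0.0 || x < 0.0 || z > nz - 1.0 || y > ny - 1.0 ||
      x > nx - 1.0)
    return fill;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 == nz - 1) z0--;
  if (y0 == ny - 1) y0--;
  if (x0 == nx - 1) x0--;
  const double fz = z - z0, fy = y - y0, fx = x - x0;
  const double c000 = v(z0, y0, x0),     c100 = v(z0 + 1, y0, x0);
  const double c010 = v(z0, y0 + 1, x0), c110 = v(z0 + 1, y0 + 1, x0);
  const double c001 = v(z0, y0, x0 + 1), c101 = v(z0 + 1, y0, x0 + 1);
  const double c011 = v(z0, y0 + 1, x0 + 1), c111 = v(z0 + 1, y0 + 1, x0 + 1);
  const double c00 = c000 * (1 - fz) + c100 * fz;
  const double c10 = c010 * (1 - fz) + c110 * fz;
  const double c01 = c001 * (1 - fz) + c101 * fz;
  const double c11 = c011 * (1 - fz) + c111 * fz;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

// Value and analytic gradient of the trilinear interpolant (the exact
// derivative of the interpolation model, needed for Lucas-Kanade).
static inline void trilinear_grad(const arma::cube& v, double z, double y,
                                  double x, double fill, double& val,
                                  double& gz, double& gy, double& gx) {
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  if (z < 0.0 || y < 0.0 || x < 0.0 || z > nz - 1.0 || y > ny - 1.0 ||
      x > nx - 1.0) {
    val = fill; gz = gy = gx = 0.0;
    return;
  }
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 == nz - 1) z0--;
  if (y0 == ny - 1) y0--;
  if (x0 == nx - 1) x0--;
  const double fz = z - z0, fy = y - y0, fx = x - x0;
  const double c000 = v(z0, y0, x0),     c100 = v(z0 + 1, y0, x0);
  const double c010 = v(z0, y0 + 1, x0), c110 = v(z0 + 1, y0 + 1, x0);
  const double c001 = v(z0, y0, x0 + 1), c101 = v(z0 + 1, y0, x0 + 1);
  const double c011 = v(z0, y0 + 1, x0 + 1), c111 = v(z0 + 1, y0 + 1, x0 + 1);
  const double c00 = c000 * (1 - fz) + c100 * fz;
  const double c10 = c010 * (1 - fz) + c110 * fz;
  const double c01 = c001 * (1 - fz) + c101 * fz;
  const double c11 = c011 * (1 - fz) + c111 * fz;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  val = c0 * (1 - fx) + c1 * fx;
  gx = c1 - c0;
  const double d00 = c100 - c000, d10 = c110 - c010;
  const double d01 = c101 - c001, d11 = c111 - c011;
  gz = ((d00 * (1 - fy) + d10 * fy) * (1 - fx) +
        (d01 * (1 - fy) + d11 * fy) * fx);
  const double e0 = c10 - c00, e1 = c11 - c01;
  gy = e0 * (1 - fx) + e1 * fx;
}

// [[Rcpp::export]]
arma::cube cpp_resample_affine(const arma::cube& v, const arma::mat& linear,
                               const arma::vec& translation, double fill) {
  // out(idx) = v(linear %*% idx + translation), idx 0-based (z, y, x)
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  arma::cube out(nz, ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double sz = linear(0, 0) * z + linear(0, 1) * y +
                          linear(0, 2) * x + translation(0);
        const double sy = linear(1, 0) * z + linear(1, 1) * y +
                          linear(1, 2) * x + translation(1);
        const double sx = linear(2, 0) * z + linear(2, 1) * y +
                          linear(2, 2) * x + translation(2);
        out(z, y, x) = trilinear(v, sz, sy, sx, fill);
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_warp_field(const arma::cube& v, const arma::cube& uz,
                          const arma::cube& uy, const arma::cube& ux,
                          double fill) {
  // Eulerian warp: out(x) = v(x - u(x)), u in voxels on the output grid
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  arma::cube out(nz, ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        out(z, y, x) = trilinear(v, z - uz(z, y, x), y - uy(z, y, x),
                                 x - ux(z, y, x), fill);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_line(const arma::cube& v, const arma::mat& pts) {
  // pts: n x 3 matrix of continuous 0-based (z, y, x) sample positions
  const int n = pts.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(v, pts(i, 0), pts(i, 1), pts(i, 2), NA_REAL);
  return out;
}

static inline double bilinear(const arma::mat& im, double r, double c,
                              double fill) {
  const int nr = im.n_rows, nc = im.n_cols;
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return fill;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == nr - 1) r0--;
  if (c0 == nc - 1) c0--;
  const double fr = r - r0, fc = c - c0;
  return im(r0, c0) * (1 - fr) * (1 - fc) + im(r0 + 1, c0) * fr * (1 - fc) +
         im(r0, c0 + 1) * (1 - fr) * fc + im(r0 + 1, c0 + 1) * fr * fc;
}

// [[Rcpp::export]]
arma::mat cpp_shift2d(const arma::mat& im, double dr, double dc, double fill) {
  // content moves by (+dr rows, +dc cols): out(r,c) = im(r - dr, c - dc)
  arma::mat out(im.n_rows, im.n_cols);
  for (arma::uword c = 0; c < im.n_cols; ++c)
    for (arma::uword r = 0; r < im.n_rows; ++r)
      out(r, c) = bilinear(im, (double)r - dr, (double)c - dc, fill);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_line2d(const arma::mat& im, const arma::mat& pts) {
  const int n = pts.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = bilinear(im, pts(i, 0), pts(i, 1), NA_REAL);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_project_parallel(const arma::cube& v, double angle_deg) {
  // Parallel-beam line integral: rays along the rotated x axis, detector
  // rows = z, detector columns = rotated y coordinate. Rotation about the
  // volume's (y, x) center. angle 0 -> plain sum along x.
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  const double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  arma::mat out(nz, ny, arma::fill::zeros);
  for (int t = 0; t < ny; ++t) {
    for (int s = 0; s < nx; ++s) {
      const double yy = cy + (t - cy) * ct - (s - cx) * st;
      const double xx = cx + (t - cy) * st + (s - cx) * ct;
      if (yy < 0.0 || xx < 0.0 || yy > ny - 1.0 || xx > nx - 1.0) continue;
      int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
      if (y0 == ny - 1) y0--;
      if (x0 == nx - 1) x0--;
      const double fy = yy - y0, fx = xx - x0;
      const double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
      const double w01 = (1 - fy) * fx, w11 = fy * fx;
      for (int z = 0; z < nz; ++z)
        out(z, t) += w00 * v(z, y0, x0) + w10 * v(z, y0 + 1, x0) +
                     w01 * v(z, y0, x0 + 1) + w11 * v(z, y0 + 1, x0 + 1);
    }
  }
  return out;
}

// exported for use by dvc.cpp
double trilinear_at(const arma::cube& v, double z, double y, double x,
                    double fill) {
  return trilinear(v, z, y, x, fill);
}
void trilinear_grad_at(const arma::cube& v, double z, double y, double x,
                       double fill, double& val, double& gz, double& gy,
                       double& gx) {
  trilinear_grad(v, z, y, x, fill, val, gz, gy, gx);
}
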
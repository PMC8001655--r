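// Morphology and metrology primitives: separable Gaussian smoothing (phantom
// speckle texture), connected-component labelling, exact Euclidean distance
// transform (Felzenszwalb-Huttenlocher per-axis passes), and geodesic
// diameter of a voxel mask via double-sweep Dijkstra with a 5x5x5
// neighborhood (chamfer error well under the metrology tolerance).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::cube cpp_gaussian_smooth3(const arma::cube& v, double sigma) {
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  const int h = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * h + 1);
  for (int i = -h; i <= h; ++i)
    k(i + h) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  arma::cube a = v, b(nz, ny, nx);
  for (int x = 0; x < nx; ++x)  // z axis, clamped borders
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0;
        for (int i = -h; i <= h; ++i)
          s += k(i + h) * a(std::min(std::max(z + i, 0), nz - 1), y, x);
        b(z, y, x) = s;
      }
  for (int x = 0; x < nx; ++x)  // y axis
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double s = 0;
        for (int i = -h; i <= h; ++i)
          s += k(i + h) * b(z, std::min(std::max(y + i, 0), ny - 1), x);
        a(z, y, x) = s;
      }
  for (int y = 0; y < ny; ++y)  // x axis
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int i = -h; i <= h; ++i)
          s += k(i + h) * a(z, y, std::min(std::max(x + i, 0), nx - 1));
        b(z, y, x) = s;
      }
  return b;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask,
                                   const IntegerVector& dim,
                                   int connectivity) {
  // BFS labelling, connectivity 6 or 26, labels 1..k, background 0
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  auto idx = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  };
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i0 = idx(z, y, x);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back();
          stack.pop_back();
          const int cx = (int)(cur / ((R_xlen_t)nz * ny));
          const int cy = (int)((cur / nz) % ny);
          const int cz = (int)(cur % nz);
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                if (connectivity == 6 &&
                    std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
                  continue;
                const int tz = cz + dz, ty = cy + dy, tx = cx + dx;
                if (tz < 0 || ty < 0 || tx < 0 || tz >= nz || ty >= ny ||
                    tx >= nx)
                  continue;
                const R_xlen_t t = idx(tz, ty, tx);
                if (mask[t] && !lab[t]) {
                  lab[t] = next;
                  stack.push_back(t);
                }
              }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower
// envelope), tolerant of +inf entries (rows with no background source)
static void dt1d(const std::vector<double>& f, double step,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> vtx(n);
  std::vector<double> zb(n + 1);
  auto inter = [&](int p, int q) -> double {
    if (std::isinf(f[q])) return INFINITY;
    if (std::isinf(f[p])) return -INFINITY;
    return ((f[q] + q * step * q * step) - (f[p] + p * step * p * step)) /
           (2.0 * step * (q - p));
  };
  int k = 0;
  vtx[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = inter(vtx[k], q);
    while (k > 0 && s <= zb[k]) {
      --k;
      s = inter(vtx[k], q);
    }
    if (k == 0 && s == -INFINITY) {
      vtx[0] = q;  // new parabola dominates everywhere seen so far
      zb[1] = INFINITY;
    } else {
      ++k;
      vtx[k] = q;
      zb[k] = s;
      zb[k + 1] = INFINITY;
    }
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q * step) ++j;
    const double diff = (q - vtx[j]) * step;
    d[q] = diff * diff + f[vtx[j]];
  }
}

// [[Rcpp::export]]
arma::cube cpp_edt(const LogicalVector& mask, const IntegerVector& dim,
                   const NumericVector& voxel_size) {
  // Euclidean distance (physical units) from each foreground voxel to the
  // nearest background voxel center; 0 on background. Domain border is NOT
  // treated as background.
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  arma::cube d(nz, ny, nx);
  auto idx = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        d(z, y, x) = mask[idx(z, y, x)] ? INFINITY : 0.0;
  std::vector<double> f, out;
  // z pass
  f.resize(nz); out.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d(z, y, x);
      dt1d(f, voxel_size[0], out);
      for (int z = 0; z < nz; ++z) d(z, y, x) = out[z];
    }
  // y pass
  f.resize(ny); out.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d(z, y, x);
      dt1d(f, voxel_size[1], out);
      for (int y = 0; y < ny; ++y) d(z, y, x) = out[y];
    }
  // x pass
  f.resize(nx); out.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d(z, y, x);
      dt1d(f, voxel_size[2], out);
      for (int x = 0; x < nx; ++x) d(z, y, x) = out[x];
    }
  return arma::sqrt(d);
}

// Dijkstra over mask voxels with a 5x5x5 neighborhood, physical edge lengths
static std::vector<double> geo_dist(const std::vector<int>& zs,
                                    const std::vector<int>& ys,
                                    const std::vector<int>& xs,
                                    const std::map<long long, int>& lookup,
                                    long long keymul_y, long long keymul_x,
                                    const NumericVector& vox, int start) {
  const int n = (int)zs.size();
  std::vector<double> dist(n, INFINITY);
  using QE = std::pair<double, int>;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> q;
  dist[start] = 0.0;
  q.push({0.0, start});
  while (!q.empty()) {
    auto [dcur, i] = q.top();
    q.pop();
    if (dcur > dist[i]) continue;
    for (int dx = -2; dx <= 2; ++dx)
      for (int dy = -2; dy <= 2; ++dy)
        for (int dz = -2; dz <= 2; ++dz) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          const long long key = (long long)(zs[i] + dz) +
                                keymul_y * (ys[i] + dy) +
                                keymul_x * (xs[i] + dx);
          auto it = lookup.find(key);
          if (it == lookup.end()) continue;
          const int j = it->second;
          const double w = std::sqrt(
              dz * vox[0] * dz * vox[0] + dy * vox[1] * dy * vox[1] +
              dx * vox[2] * dx * vox[2]);
          if (dist[i] + w < dist[j]) {
            dist[j] = dist[i] + w;
            q.push({dist[j], j});
          }
        }
  }
  return dist;
}

// [[Rcpp::export]]
List cpp_geodesic_diameter(const arma::imat& coords,
                           const NumericVector& voxel_size) {
  // coords: N x 3 (z, y, x) voxel indices of a connected mask. Double-sweep:
  // farthest voxel from an arbitrary start, then farthest from that one.
  const int n = coords.n_rows;
  if (n == 0) stop("empty mask");
  std::vector<int> zs(n), ys(n), xs(n);
  long long zmax = 0, ymax = 0;
  for (int i = 0; i < n; ++i) {
    zs[i] = (int)coords(i, 0);
    ys[i] = (int)coords(i, 1);
    xs[i] = (int)coords(i, 2);
    zmax = std::max(zmax, (long long)zs[i]);
    ymax = std::max(ymax, (long long)ys[i]);
  }
  const long long keymul_y = zmax + 5, keymul_x = keymul_y * (ymax + 5);
  std::map<long long, int> lookup;
  for (int i = 0; i < n; ++i)
    lookup[(long long)zs[i] + keymul_y * ys[i] + keymul_x * xs[i]] = i;
  auto d0 = geo_dist(zs, ys, xs, lookup, keymul_y, keymul_x, voxel_size, 0);
  int a = 0;
  for (int i = 0; i < n; ++i)
    if (std::isfinite(d0[i]) && d0[i] > d0[a]) a = i;
  if (!std::isfinite(d0[a]) && n > 1) stop("mask is not connected");
  auto d1 = geo_dist(zs, ys, xs, lookup, keymul_y, keymul_x, voxel_size, a);
  int b = a;
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    if (std::isfinite(d1[i]) && d1[i] > best) { best = d1[i]; b = i; }
  return List::create(_["length"] = best, _["start"] = a + 1,
                      _["end"] = b + 1);
}
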
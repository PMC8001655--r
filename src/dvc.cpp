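// DVC engine hot loops: 3D median prefilter, zero-mean NCC between cubic
// windows, steepest-gradient integer search, 3D Lucas-Kanade sub-voxel
// refinement with a 12-parameter local affine warp, batched node tracking,
// and the 2D NCC map used for reference-frame DIC.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double trilinear_at(const arma::cube& v, double z, double y, double x,
                    double fill);
void trilinear_grad_at(const arma::cube& v, double z, double y, double x,
                       double fill, double& val, double& gz, double& gy,
                       double& gx);

// [[Rcpp::export]]
arma::cube cpp_median_filter3(const arma::cube& v, int kernel) {
  // per-voxel median over a kernel^3 cube, edge-replicated borders
  const int nz = v.n_rows, ny = v.n_cols, nx = v.n_slices;
  const int h = kernel / 2;
  arma::cube out(nz, ny, nx);
  std::vector<double> buf;
  buf.reserve((size_t)kernel * kernel * kernel);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dx = -h; dx <= h; ++dx) {
          int xx = std::min(std::max(x + dx, 0), nx - 1);
          for (int dy = -h; dy <= h; ++dy) {
            int yy = std::min(std::max(y + dy, 0), ny - 1);
            for (int dz = -h; dz <= h; ++dz) {
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              buf.push_back(v(zz, yy, xx));
            }
          }
        }
        const size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1,
                           buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        out(z, y, x) = med;
      }
  return out;
}

// Window offsets for edge length w: lo..hi around the node, half-open split
// for even w (lo = -floor((w-1)/2), hi = lo + w - 1).
static inline void win_bounds(int w, int& lo, int& hi) {
  lo = -((w - 1) / 2);
  hi = lo + w - 1;
}

// Zero-mean (Pearson) NCC between the reference window at `node` and the
// deformed window displaced by integer (dz, dy, dx). Returns NA when either
// window has zero variance, -2 when a window leaves its volume.
static double ncc_at(const arma::cube& ref, const arma::cube& def, int nz0,
                     int ny0, int nx0, int w, int dz, int dy, int dx) {
  const int nz = ref.n_rows, ny = ref.n_cols, nx = ref.n_slices;
  int lo, hi;
  win_bounds(w, lo, hi);
  if (nz0 + lo < 0 || ny0 + lo < 0 || nx0 + lo < 0 || nz0 + hi >= nz ||
      ny0 + hi >= ny || nx0 + hi >= nx)
    return -2.0;
  const int dnz = def.n_rows, dny = def.n_cols, dnx = def.n_slices;
  if (nz0 + dz + lo < 0 || ny0 + dy + lo < 0 || nx0 + dx + lo < 0 ||
      nz0 + dz + hi >= dnz || ny0 + dy + hi >= dny || nx0 + dx + hi >= dnx)
    return -2.0;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  const int n = w * w * w;
  for (int ox = lo; ox <= hi; ++ox)
    for (int oy = lo; oy <= hi; ++oy)
      for (int oz = lo; oz <= hi; ++oz) {
        const double a = ref(nz0 + oz, ny0 + oy, nx0 + ox);
        const double b = def(nz0 + dz + oz, ny0 + dy + oy, nx0 + dx + ox);
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
  const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0.0 || vb <= 0.0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// [[Rcpp::export]]
double cpp_ncc(const arma::cube& ref, const arma::cube& def,
               const arma::ivec& node, int w, const arma::ivec& disp) {
  double r = ncc_at(ref, def, node(0), node(1), node(2), w, disp(0), disp(1),
                    disp(2));
  if (r <= -1.5) stop("correlation window out of volume bounds");
  return r;
}

// Coarse-to-fine steepest-gradient climb over integer displacements: hill
// climbing on the 26-neighborhood at strides halving from ~radius down to
// 1, bounded by |d - init| <= radius per axis. The coarse strides step
// across the shallow local maxima a smooth-texture NCC surface exhibits.
static double climb_search(const arma::cube& ref, const arma::cube& def,
                           int z0, int y0, int x0, int w, int radius,
                           const arma::ivec& init, int& bz, int& by,
                           int& bx) {
  bz = init(0); by = init(1); bx = init(2);
  double best = ncc_at(ref, def, z0, y0, x0, w, bz, by, bx);
  if (best <= -1.5 || ISNAN(best)) return best;
  int stride0 = 1;
  while (stride0 * 2 <= std::max(1, radius)) stride0 *= 2;
  for (int stride = stride0; stride >= 1; stride /= 2) {
    bool improved = true;
    while (improved) {
      improved = false;
      const int cz = bz, cy = by, cx = bx;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            const int tz = cz + dz * stride, ty = cy + dy * stride,
                      tx = cx + dx * stride;
            if (std::abs(tz - (int)init(0)) > radius ||
                std::abs(ty - (int)init(1)) > radius ||
                std::abs(tx - (int)init(2)) > radius)
              continue;
            const double r = ncc_at(ref, def, z0, y0, x0, w, tz, ty, tx);
            if (!ISNAN(r) && r > -1.5 && r > best) {
              best = r; bz = tz; by = ty; bx = tx; improved = true;
            }
          }
    }
  }
  if (best < 0.9) {
    // likely trapped on a spurious local maximum of the smooth NCC
    // surface: coarse stride-2 scan of the bounded cube, then re-climb
    int sz = bz, sy = by, sx = bx;
    double sbest = best;
    for (int dx = -radius; dx <= radius; dx += 2)
      for (int dy = -radius; dy <= radius; dy += 2)
        for (int dz = -radius; dz <= radius; dz += 2) {
          const double r = ncc_at(ref, def, z0, y0, x0, w, init(0) + dz,
                                  init(1) + dy, init(2) + dx);
          if (!ISNAN(r) && r > -1.5 && r > sbest) {
            sbest = r;
            sz = init(0) + dz; sy = init(1) + dy; sx = init(2) + dx;
          }
        }
    bz = sz; by = sy; bx = sx;
    best = sbest;
    bool improved = true;
    while (improved) {
      improved = false;
      const int cz = bz, cy = by, cx = bx;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            const int tz = cz + dz, ty = cy + dy, tx = cx + dx;
            if (std::abs(tz - (int)init(0)) > radius ||
                std::abs(ty - (int)init(1)) > radius ||
                std::abs(tx - (int)init(2)) > radius)
              continue;
            const double r = ncc_at(ref, def, z0, y0, x0, w, tz, ty, tx);
            if (!ISNAN(r) && r > -1.5 && r > best) {
              best = r; bz = tz; by = ty; bx = tx; improved = true;
            }
          }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_integer_search(const arma::cube& ref, const arma::cube& def,
                        const arma::ivec& node, int w, int radius,
                        const arma::ivec& init, bool exhaustive) {
  const int z0 = node(0), y0 = node(1), x0 = node(2);
  int bz = init(0), by = init(1), bx = init(2);
  double best = ncc_at(ref, def, z0, y0, x0, w, bz, by, bx);
  if (best <= -1.5) stop("correlation window out of volume bounds at node");
  if (ISNAN(best)) stop("zero-variance correlation window (NCC undefined)");
  if (exhaustive) {
    for (int dx = init(2) - radius; dx <= init(2) + radius; ++dx)
      for (int dy = init(1) - radius; dy <= init(1) + radius; ++dy)
        for (int dz = init(0) - radius; dz <= init(0) + radius; ++dz) {
          const double r = ncc_at(ref, def, z0, y0, x0, w, dz, dy, dx);
          if (!ISNAN(r) && r > -1.5 && r > best) {
            best = r; bz = dz; by = dy; bx = dx;
          }
        }
  } else {
    best = climb_search(ref, def, z0, y0, x0, w, radius, init, bz, by, bx);
  }
  return List::create(_["disp"] = IntegerVector::create(bz, by, bx),
                      _["ncc"] = best);
}

// Gauss-Newton minimization of SSD between the reference window and the
// deformed volume sampled under warp x -> node + d + u + A d (d = offset in
// the window, u = translation, A = affine deviation). 12 parameters:
// p = (u_z, u_y, u_x, A_zz, A_zy, A_zx, A_yz, ..., A_xx).
// SSD of the warped window; +inf when any sample leaves the volume
static double warp_ssd(const arma::cube& ref, const arma::cube& def, int z0,
                       int y0, int x0, int lo, int hi, const arma::vec& u,
                       const arma::mat& A) {
  double ssd = 0.0;
  for (int ox = lo; ox <= hi; ++ox)
    for (int oy = lo; oy <= hi; ++oy)
      for (int oz = lo; oz <= hi; ++oz) {
        const double rz = z0 + oz, ry = y0 + oy, rx = x0 + ox;
        const double wz = rz + u(0) + A(0, 0) * oz + A(0, 1) * oy + A(0, 2) * ox;
        const double wy = ry + u(1) + A(1, 0) * oz + A(1, 1) * oy + A(1, 2) * ox;
        const double wx = rx + u(2) + A(2, 0) * oz + A(2, 1) * oy + A(2, 2) * ox;
        const double val = trilinear_at(def, wz, wy, wx, NA_REAL);
        if (ISNAN(val)) return INFINITY;
        const double err = ref((int)rz, (int)ry, (int)rx) - val;
        ssd += err * err;
      }
  return ssd;
}

static List lk_refine(const arma::cube& ref, const arma::cube& def, int z0,
                      int y0, int x0, int w, const arma::vec& uinit,
                      double tol, int maxit) {
  int lo, hi;
  win_bounds(w, lo, hi);
  const int n = w * w * w;
  arma::vec u = uinit;
  arma::mat A(3, 3, arma::fill::zeros);
  const double half = w / 2.0;
  bool converged = false;
  int iters = 0;
  arma::vec J(12);
  double ssd_cur = warp_ssd(ref, def, z0, y0, x0, lo, hi, u, A);
  for (int it = 0; it < maxit && std::isfinite(ssd_cur); ++it) {
    iters = it + 1;
    arma::mat H(12, 12, arma::fill::zeros);
    arma::vec g(12, arma::fill::zeros);
    bool oob = false;
    for (int ox = lo; ox <= hi && !oob; ++ox)
      for (int oy = lo; oy <= hi && !oob; ++oy)
        for (int oz = lo; oz <= hi; ++oz) {
          const double rz = z0 + oz, ry = y0 + oy, rx = x0 + ox;
          const double wz = rz + u(0) + A(0, 0) * oz + A(0, 1) * oy + A(0, 2) * ox;
          const double wy = ry + u(1) + A(1, 0) * oz + A(1, 1) * oy + A(1, 2) * ox;
          const double wx = rx + u(2) + A(2, 0) * oz + A(2, 1) * oy + A(2, 2) * ox;
          double val, gz, gy, gx;
          trilinear_grad_at(def, wz, wy, wx, NA_REAL, val, gz, gy, gx);
          if (ISNAN(val)) { oob = true; break; }
          const double err = ref((int)rz, (int)ry, (int)rx) - val;
          J(0) = gz; J(1) = gy; J(2) = gx;
          J(3) = gz * oz; J(4) = gz * oy; J(5) = gz * ox;
          J(6) = gy * oz; J(7) = gy * oy; J(8) = gy * ox;
          J(9) = gx * oz; J(10) = gx * oy; J(11) = gx * ox;
          for (int a = 0; a < 12; ++a) {
            g(a) += J(a) * err;
            for (int b = a; b < 12; ++b) H(a, b) += J(a) * J(b);
          }
        }
    if (oob) break;
    H = arma::symmatu(H);
    arma::vec dp;
    const bool ok = arma::solve(dp, H, g, arma::solve_opts::no_approx);
    if (!ok || !dp.is_finite()) break;
    // backtracking line search on the SSD: the piecewise-linear interpolant
    // makes pure Gauss-Newton limit-cycle near the optimum
    double scale = 1.0;
    arma::vec u_try;
    arma::mat A_try(3, 3);
    double ssd_try = INFINITY;
    int bt = 0;
    for (; bt < 10; ++bt) {
      u_try = u;
      A_try = A;
      u_try(0) += scale * dp(0);
      u_try(1) += scale * dp(1);
      u_try(2) += scale * dp(2);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) A_try(i, j) += scale * dp(3 + 3 * i + j);
      ssd_try = warp_ssd(ref, def, z0, y0, x0, lo, hi, u_try, A_try);
      if (ssd_try <= ssd_cur) break;
      scale *= 0.5;
    }
    if (!(ssd_try <= ssd_cur)) {
      // no improving step exists along dp: stationary point reached
      converged = true;
      break;
    }
    const double improved = ssd_cur - ssd_try;
    u = u_try;
    A = A_try;
    ssd_cur = ssd_try;
    // update magnitude in voxels: translation plus affine effect at the
    // window half-width
    const double step =
        scale * (std::sqrt(dp(0) * dp(0) + dp(1) * dp(1) + dp(2) * dp(2)) +
                 half * std::sqrt(arma::dot(dp.subvec(3, 11),
                                            dp.subvec(3, 11))));
    if (step < tol ||
        improved <= 1e-12 * std::max(ssd_cur, (double)n)) {
      converged = true;
      break;
    }
  }
  // NCC at the converged warp (diagnostic; Pearson on warped samples)
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  bool valid = true;
  for (int ox = lo; ox <= hi && valid; ++ox)
    for (int oy = lo; oy <= hi && valid; ++oy)
      for (int oz = lo; oz <= hi; ++oz) {
        const double rz = z0 + oz, ry = y0 + oy, rx = x0 + ox;
        const double wz = rz + u(0) + A(0, 0) * oz + A(0, 1) * oy + A(0, 2) * ox;
        const double wy = ry + u(1) + A(1, 0) * oz + A(1, 1) * oy + A(1, 2) * ox;
        const double wx = rx + u(2) + A(2, 0) * oz + A(2, 1) * oy + A(2, 2) * ox;
        const double b = trilinear_at(def, wz, wy, wx, NA_REAL);
        if (ISNAN(b)) { valid = false; break; }
        const double a = ref((int)rz, (int)ry, (int)rx);
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
  double ncc = NA_REAL;
  if (valid) {
    const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
    if (va > 0 && vb > 0) ncc = (sab - sa * sb / n) / std::sqrt(va * vb);
  }
  return List::create(_["u"] = NumericVector::create(u(0), u(1), u(2)),
                      _["A"] = A, _["converged"] = converged,
                      _["iterations"] = iters, _["ncc"] = ncc);
}

// Inverse-synthesis refinement at one node: the Gauss-Newton fit warps the
// pristine reference volume onto the deformed-state window (centered at
// node + round(uinit)), then the fitted inverse map is inverted to forward
// displacement u and local affine deviation A. Sampling only the
// un-resampled reference removes the interpolation-model bias a forward
// fit suffers on resampled data.
static void refine_node(const arma::cube& ref, const arma::cube& def,
                        int z0, int y0, int x0, int w,
                        const arma::vec& uinit, double tol, int maxit,
                        arma::vec& u_out, arma::mat& A_out, double& ncc_out,
                        bool& conv_out, int& iters_out) {
  arma::ivec m = {(arma::sword)(z0 + std::lround(uinit(0))),
                  (arma::sword)(y0 + std::lround(uinit(1))),
                  (arma::sword)(x0 + std::lround(uinit(2)))};
  List core = lk_refine(def, ref, (int)m(0), (int)m(1), (int)m(2), w,
                        -uinit, tol, maxit);
  NumericVector vv = core["u"];
  arma::mat B = core["A"];
  ncc_out = as<double>(core["ncc"]);
  conv_out = as<bool>(core["converged"]);
  iters_out = as<int>(core["iterations"]);
  // def(y) = ref(y + v + B (y - m)); forward map: y = (I+B)^-1 (x - v + B m)
  arma::mat IB = arma::eye(3, 3) + B;
  arma::mat F;
  if (!arma::inv(F, IB)) {
    conv_out = false;
    u_out = {NA_REAL, NA_REAL, NA_REAL};
    A_out.zeros(3, 3);
    return;
  }
  arma::vec x = {(double)z0, (double)y0, (double)x0};
  arma::vec v = {vv[0], vv[1], vv[2]};
  arma::vec mm = {(double)m(0), (double)m(1), (double)m(2)};
  u_out = F * (x - v + B * mm) - x;
  A_out = F - arma::eye(3, 3);
}

// [[Rcpp::export]]
List cpp_lk_refine(const arma::cube& ref, const arma::cube& def,
                   const arma::ivec& node, int w, const arma::vec& uinit,
                   double tol, int maxit) {
  arma::vec u(3);
  arma::mat A(3, 3);
  double ncc;
  bool conv;
  int iters;
  refine_node(ref, def, node(0), node(1), node(2), w, uinit, tol, maxit, u,
              A, ncc, conv, iters);
  return List::create(_["u"] = NumericVector::create(u(0), u(1), u(2)),
                      _["A"] = A, _["converged"] = conv,
                      _["iterations"] = iters, _["ncc"] = ncc);
}

// [[Rcpp::export]]
List cpp_track_nodes(const arma::cube& ref, const arma::cube& def,
                     const arma::imat& nodes, const arma::mat& uinit, int w,
                     int radius, double tol, int maxit) {
  // nodes: N x 3 integer (z, y, x) 0-based; uinit: N x 3 initial guess.
  // Integer search seeded at round(uinit), then sub-voxel refinement.
  const int n = nodes.n_rows;
  arma::mat u(n, 3);
  NumericVector ncc(n);
  LogicalVector conv(n);
  for (int i = 0; i < n; ++i) {
    const int z0 = nodes(i, 0), y0 = nodes(i, 1), x0 = nodes(i, 2);
    arma::ivec init(3);
    init(0) = (arma::sword)std::lround(uinit(i, 0));
    init(1) = (arma::sword)std::lround(uinit(i, 1));
    init(2) = (arma::sword)std::lround(uinit(i, 2));
    int bz, by, bx;
    double best = climb_search(ref, def, z0, y0, x0, w, radius, init, bz,
                               by, bx);
    const bool ok = !(best <= -1.5) && !ISNAN(best);
    if (!ok) {
      u(i, 0) = NA_REAL; u(i, 1) = NA_REAL; u(i, 2) = NA_REAL;
      ncc[i] = NA_REAL;
      conv[i] = false;
      continue;
    }
    arma::vec ui = {(double)bz, (double)by, (double)bx};
    arma::vec uo(3);
    arma::mat Ao(3, 3);
    double nco;
    bool cvo;
    int ito;
    refine_node(ref, def, z0, y0, x0, w, ui, tol, maxit, uo, Ao, nco, cvo,
                ito);
    u(i, 0) = uo(0); u(i, 1) = uo(1); u(i, 2) = uo(2);
    ncc[i] = nco;
    conv[i] = cvo;
  }
  return List::create(_["u"] = u, _["ncc"] = ncc, _["converged"] = conv);
}

// [[Rcpp::export]]
NumericVector cpp_lk2d(const arma::mat& ref, const arma::mat& img,
                       int margin, const arma::vec& init, double tol,
                       int maxit) {
  // translation-only 2D Lucas-Kanade: minimize sum over the interior
  // template of (ref(r,c) - img(r + u0, c + u1))^2 by Gauss-Newton with
  // bilinear sampling and its analytic gradient; backtracking on the SSD
  const int nr = ref.n_rows, nc = ref.n_cols;
  const int r0 = margin, r1 = nr - margin, c0 = margin, c1 = nc - margin;
  arma::vec u = init;
  auto sample = [&](double r, double c, double& val, double& gr,
                    double& gc) {
    if (r < 0 || c < 0 || r > img.n_rows - 1.0 || c > img.n_cols - 1.0) {
      val = NA_REAL;
      return;
    }
    int ri = (int)std::floor(r), ci = (int)std::floor(c);
    if (ri == (int)img.n_rows - 1) ri--;
    if (ci == (int)img.n_cols - 1) ci--;
    const double fr = r - ri, fc = c - ci;
    const double a = img(ri, ci), b = img(ri + 1, ci);
    const double d = img(ri, ci + 1), e = img(ri + 1, ci + 1);
    val = a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + d * (1 - fr) * fc +
          e * fr * fc;
    gr = (b - a) * (1 - fc) + (e - d) * fc;
    gc = (d - a) * (1 - fr) + (e - b) * fr;
  };
  auto ssd_at = [&](const arma::vec& uu) -> double {
    double s = 0, v, gr, gc;
    for (int c = c0; c < c1; ++c)
      for (int r = r0; r < r1; ++r) {
        sample(r + uu(0), c + uu(1), v, gr, gc);
        if (ISNAN(v)) return INFINITY;
        const double e2 = ref(r, c) - v;
        s += e2 * e2;
      }
    return s;
  };
  double ssd = ssd_at(u);
  for (int it = 0; it < maxit && std::isfinite(ssd); ++it) {
    double h00 = 0, h01 = 0, h11 = 0, g0 = 0, g1 = 0;
    bool oob = false;
    for (int c = c0; c < c1 && !oob; ++c)
      for (int r = r0; r < r1; ++r) {
        double v, gr, gc;
        sample(r + u(0), c + u(1), v, gr, gc);
        if (ISNAN(v)) { oob = true; break; }
        const double err = ref(r, c) - v;
        h00 += gr * gr; h01 += gr * gc; h11 += gc * gc;
        g0 += gr * err; g1 += gc * err;
      }
    if (oob) break;
    const double det = h00 * h11 - h01 * h01;
    if (det <= 0) break;
    double d0 = (h11 * g0 - h01 * g1) / det;
    double d1 = (h00 * g1 - h01 * g0) / det;
    double scale = 1.0;
    arma::vec u_try(2);
    double ssd_try = INFINITY;
    for (int bt = 0; bt < 10; ++bt) {
      u_try(0) = u(0) + scale * d0;
      u_try(1) = u(1) + scale * d1;
      ssd_try = ssd_at(u_try);
      if (ssd_try <= ssd) break;
      scale *= 0.5;
    }
    if (!(ssd_try <= ssd)) break;
    const double step = scale * std::sqrt(d0 * d0 + d1 * d1);
    u = u_try;
    ssd = ssd_try;
    if (step < tol) break;
  }
  return NumericVector::create(u(0), u(1));
}

// [[Rcpp::export]]
arma::mat cpp_xcorr2(const arma::mat& ref, const arma::mat& img, int radius,
                     int margin) {
  // Pearson NCC of a fixed interior template of `ref` (margin pixels in
  // from every edge) against `img` sampled at integer shifts (dr, dc).
  // The fixed template keeps the compared region constant across shifts
  // and stays clear of borders contaminated by shift fill values. Output
  // is a (2*radius+1)^2 map, row index = dr + radius; img content shifted
  // by (+dr, +dc) relative to ref peaks at (dr, dc).
  const int nr = ref.n_rows, nc = ref.n_cols;
  if (margin < radius) margin = radius;
  const int r0 = margin, r1 = nr - margin;
  const int c0 = margin, c1 = nc - margin;
  arma::mat out(2 * radius + 1, 2 * radius + 1);
  out.fill(NA_REAL);
  const long n = (long)(r1 - r0) * (c1 - c0);
  if (n < 9) stop("frames too small for the requested search margin");
  double sa = 0, saa = 0;
  for (int c = c0; c < c1; ++c)
    for (int r = r0; r < r1; ++r) {
      const double a = ref(r, c);
      sa += a;
      saa += a * a;
    }
  const double va = saa - sa * sa / n;
  for (int dc = -radius; dc <= radius; ++dc)
    for (int dr = -radius; dr <= radius; ++dr) {
      double sb = 0, sbb = 0, sab = 0;
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r) {
          const double b = img(r + dr, c + dc);
          sb += b; sbb += b * b; sab += ref(r, c) * b;
        }
      const double vb = sbb - sb * sb / n;
      if (va <= 0 || vb <= 0) continue;
      out(dr + radius, dc + radius) = (sab - sa * sb / n) / std::sqrt(va * vb);
    }
  return out;
}
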
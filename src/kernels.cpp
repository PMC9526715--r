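// Low-level numeric kernels for the 3D segmentation engine.
//
// Tensor layout: column-major R arrays with dim = (C, Z, Y, X) for feature
// maps and (Z, Y, X) for scalar volumes, so the channel index is the
// fastest-varying one and the inner accumulation loops over input channels
// touch contiguous memory.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  if (x.attr("dim") == R_NilValue) stop("array input required");
  return x.attr("dim");
}

// ---------------------------------------------------------------------------
// 3D convolution, stride 1, zero "same" padding for odd kernels.
// x: (Cin, Z, Y, X); w: (Cin, kz, ky, kx, Cout); b: (Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  if (xd.size() != 4 || wd.size() != 5) stop("conv3d: bad ranks");
  const int Cin = xd[0], Z = xd[1], Y = xd[2], X = xd[3];
  const int kz = wd[1], ky = wd[2], kx = wd[3], Cout = wd[4];
  if (wd[0] != Cin) stop("conv3d: channel mismatch");
  if (b.size() != Cout) stop("conv3d: bias mismatch");
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  NumericVector out(static_cast<R_xlen_t>(Cout) * Z * Y * X);
  out.attr("dim") = IntegerVector::create(Cout, Z, Y, X);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();

  for (int ox = 0; ox < X; ++ox)
    for (int oy = 0; oy < Y; ++oy)
      for (int oz = 0; oz < Z; ++oz) {
        R_xlen_t obase = static_cast<R_xlen_t>(Cout) * (oz + static_cast<R_xlen_t>(Z) * (oy + static_cast<R_xlen_t>(Y) * ox));
        for (int co = 0; co < Cout; ++co) op[obase + co] = b[co];
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox + dx - px; if (ix < 0 || ix >= X) continue;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy + dy - py; if (iy < 0 || iy >= Y) continue;
            for (int dz = 0; dz < kz; ++dz) {
              int iz = oz + dz - pz; if (iz < 0 || iz >= Z) continue;
              const double* xv = xp + static_cast<R_xlen_t>(Cin) * (iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix));
              for (int co = 0; co < Cout; ++co) {
                const double* wv = wp + static_cast<R_xlen_t>(Cin) * (dz + kz * (dy + ky * (static_cast<R_xlen_t>(dx) + kx * co)));
                double acc = 0.0;
                for (int ci = 0; ci < Cin; ++ci) acc += xv[ci] * wv[ci];
                op[obase + co] += acc;
              }
            }
          }
        }
      }
  return out;
}

// Backward pass: gradients w.r.t. input, weights and bias in one sweep.
// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), gd = dims_of(gout);
  const int Cin = xd[0], Z = xd[1], Y = xd[2], X = xd[3];
  const int kz = wd[1], ky = wd[2], kx = wd[3], Cout = wd[4];
  if (gd[0] != Cout || gd[1] != Z || gd[2] != Y || gd[3] != X) stop("conv3d_bw: shape mismatch");
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();

  for (int ox = 0; ox < X; ++ox)
    for (int oy = 0; oy < Y; ++oy)
      for (int oz = 0; oz < Z; ++oz) {
        R_xlen_t obase = static_cast<R_xlen_t>(Cout) * (oz + static_cast<R_xlen_t>(Z) * (oy + static_cast<R_xlen_t>(Y) * ox));
        for (int co = 0; co < Cout; ++co) gb[co] += gp[obase + co];
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox + dx - px; if (ix < 0 || ix >= X) continue;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy + dy - py; if (iy < 0 || iy >= Y) continue;
            for (int dz = 0; dz < kz; ++dz) {
              int iz = oz + dz - pz; if (iz < 0 || iz >= Z) continue;
              R_xlen_t xbase = static_cast<R_xlen_t>(Cin) * (iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix));
              for (int co = 0; co < Cout; ++co) {
                double g = gp[obase + co];
                if (g == 0.0) continue;
                R_xlen_t wbase = static_cast<R_xlen_t>(Cin) * (dz + kz * (dy + ky * (static_cast<R_xlen_t>(dx) + kx * co)));
                for (int ci = 0; ci < Cin; ++ci) {
                  gxp[xbase + ci] += wp[wbase + ci] * g;
                  gwp[wbase + ci] += xp[xbase + ci] * g;
                }
              }
            }
          }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Max pooling with per-axis kernel == stride (kz, ky, kx); dims must divide.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".maxpool3d_fw")]]
List maxpool3d_fw(NumericVector x, int kz, int ky, int kx) {
  IntegerVector xd = dims_of(x);
  const int C = xd[0], Z = xd[1], Y = xd[2], X = xd[3];
  if (Z % kz || Y % ky || X % kx) stop("maxpool3d: extent not divisible by pooling kernel");
  const int Zo = Z / kz, Yo = Y / ky, Xo = X / kx;
  NumericVector out(static_cast<R_xlen_t>(C) * Zo * Yo * Xo);
  out.attr("dim") = IntegerVector::create(C, Zo, Yo, Xo);
  IntegerVector arg(out.size());
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  R_xlen_t o = 0;
  for (int ox = 0; ox < Xo; ++ox)
    for (int oy = 0; oy < Yo; ++oy)
      for (int oz = 0; oz < Zo; ++oz)
        for (int c = 0; c < C; ++c, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bidx = -1;
          for (int dx = 0; dx < kx; ++dx)
            for (int dy = 0; dy < ky; ++dy)
              for (int dz = 0; dz < kz; ++dz) {
                R_xlen_t idx = c + static_cast<R_xlen_t>(C) * ((oz * kz + dz) + static_cast<R_xlen_t>(Z) * ((oy * ky + dy) + static_cast<R_xlen_t>(Y) * (ox * kx + dx)));
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
          op[o] = best;
          ap[o] = static_cast<int>(bidx);
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bw")]]
NumericVector maxpool3d_bw(NumericVector gout, IntegerVector argmax, IntegerVector xdim) {
  R_xlen_t n = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  return gx;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour upsampling by integer factors (kz, ky, kx).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".upsample_nn_fw")]]
NumericVector upsample_nn_fw(NumericVector x, int kz, int ky, int kx) {
  IntegerVector xd = dims_of(x);
  const int C = xd[0], Z = xd[1], Y = xd[2], X = xd[3];
  const int Zo = Z * kz, Yo = Y * ky, Xo = X * kx;
  NumericVector out(static_cast<R_xlen_t>(C) * Zo * Yo * Xo);
  out.attr("dim") = IntegerVector::create(C, Zo, Yo, Xo);
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t o = 0;
  for (int ox = 0; ox < Xo; ++ox)
    for (int oy = 0; oy < Yo; ++oy)
      for (int oz = 0; oz < Zo; ++oz) {
        const double* xv = xp + static_cast<R_xlen_t>(C) * ((oz / kz) + static_cast<R_xlen_t>(Z) * ((oy / ky) + static_cast<R_xlen_t>(Y) * (ox / kx)));
        for (int c = 0; c < C; ++c, ++o) op[o] = xv[c];
      }
  return out;
}

// [[Rcpp::export(name = ".upsample_nn_bw")]]
NumericVector upsample_nn_bw(NumericVector gout, int kz, int ky, int kx) {
  IntegerVector gd = dims_of(gout);
  const int C = gd[0], Zo = gd[1], Yo = gd[2], Xo = gd[3];
  const int Z = Zo / kz, Y = Yo / ky, X = Xo / kx;
  NumericVector gx(static_cast<R_xlen_t>(C) * Z * Y * X);
  gx.attr("dim") = IntegerVector::create(C, Z, Y, X);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  R_xlen_t o = 0;
  for (int ox = 0; ox < Xo; ++ox)
    for (int oy = 0; oy < Yo; ++oy)
      for (int oz = 0; oz < Zo; ++oz) {
        double* xv = xp + static_cast<R_xlen_t>(C) * ((oz / kz) + static_cast<R_xlen_t>(Z) * ((oy / ky) + static_cast<R_xlen_t>(Y) * (ox / kx)));
        for (int c = 0; c < C; ++c, ++o) xv[c] += gp[o];
      }
  return gx;
}

// ---------------------------------------------------------------------------
// Affine resampling of a scalar (Z, Y, X) volume.
// For each output voxel index o (0-based), the source index is A %*% o + off,
// sampled with trilinear (mode 0) or nearest-neighbour (mode 1) interpolation;
// source coordinates outside the grid read `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector vol, IntegerVector odim,
                              NumericMatrix A, NumericVector off,
                              int mode, double fill, int clamp) {
  IntegerVector vd = dims_of(vol);
  const int Z = vd[0], Y = vd[1], X = vd[2];
  const int Zo = odim[0], Yo = odim[1], Xo = odim[2];
  NumericVector out(static_cast<R_xlen_t>(Zo) * Yo * Xo);
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo);
  const double* vp = vol.begin();
  double* op = out.begin();
  R_xlen_t o = 0;
  for (int ox = 0; ox < Xo; ++ox)
    for (int oy = 0; oy < Yo; ++oy)
      for (int oz = 0; oz < Zo; ++oz, ++o) {
        double sz = A(0, 0) * oz + A(0, 1) * oy + A(0, 2) * ox + off[0];
        double sy = A(1, 0) * oz + A(1, 1) * oy + A(1, 2) * ox + off[1];
        double sx = A(2, 0) * oz + A(2, 1) * oy + A(2, 2) * ox + off[2];
        if (clamp) {
          sz = std::min(std::max(sz, 0.0), static_cast<double>(Z - 1));
          sy = std::min(std::max(sy, 0.0), static_cast<double>(Y - 1));
          sx = std::min(std::max(sx, 0.0), static_cast<double>(X - 1));
        }
        if (mode == 1) {
          long iz = std::lround(sz), iy = std::lround(sy), ix = std::lround(sx);
          if (iz < 0 || iz >= Z || iy < 0 || iy >= Y || ix < 0 || ix >= X) { op[o] = fill; continue; }
          op[o] = vp[iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix)];
        } else {
          if (sz < -1.0 || sz > Z || sy < -1.0 || sy > Y || sx < -1.0 || sx > X) { op[o] = fill; continue; }
          int z0 = static_cast<int>(std::floor(sz)), y0 = static_cast<int>(std::floor(sy)), x0 = static_cast<int>(std::floor(sx));
          double fz = sz - z0, fy = sy - y0, fx = sx - x0;
          double acc = 0.0;
          for (int dx = 0; dx <= 1; ++dx)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dz = 0; dz <= 1; ++dz) {
                int iz = z0 + dz, iy = y0 + dy, ix = x0 + dx;
                double wgt = (dz ? fz : 1.0 - fz) * (dy ? fy : 1.0 - fy) * (dx ? fx : 1.0 - fx);
                if (wgt == 0.0) continue;
                double v = (iz < 0 || iz >= Z || iy < 0 || iy >= Y || ix < 0 || ix >= X)
                  ? fill
                  : vp[iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix)];
                acc += wgt * v;
              }
          op[o] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm, one 1D pass per axis). `sites` marks
// voxels at distance zero; distances are measured between voxel centers in
// physical units given by `spacing` = (sz, sy, sx) matching the (Z, Y, X) axes.
// ---------------------------------------------------------------------------

static void dt1d(double* f, double* d, int* v, double* zbnd, int n, double s) {
  // f: squared distances along one scan line; parabola sites sit at q*s.
  // Voxels with f == INF contribute no parabola; if the leading envelope
  // entry is infinite it is replaced by the first finite parabola.
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zbnd[0] = -INF;
  zbnd[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double qq = q * s;
    while (true) {
      double vv = v[k] * s;
      double sep = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (sep <= zbnd[k]) { --k; continue; }  // zbnd[0] = -INF keeps k >= 0
      ++k;
      v[k] = q;
      zbnd[k] = sep;
      zbnd[k + 1] = INF;
      break;
    }
  }
  int k2 = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * s;
    while (zbnd[k2 + 1] < qq) ++k2;
    double vv = v[k2] * s;
    double base = f[v[k2]];
    d[q] = (base == INF) ? INF : (qq - vv) * (qq - vv) + base;
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector sites, IntegerVector dim, NumericVector spacing) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = static_cast<R_xlen_t>(Z) * Y * X;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = sites[i] ? 0.0 : INF;
  int m = std::max(Z, std::max(Y, X));
  std::vector<double> f(m), d(m), zb(m + 1);
  std::vector<int> v(m);

  // pass along z (fastest axis)
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      R_xlen_t base = static_cast<R_xlen_t>(Z) * (y + static_cast<R_xlen_t>(Y) * x);
      for (int z = 0; z < Z; ++z) f[z] = g[base + z];
      dt1d(f.data(), d.data(), v.data(), zb.data(), Z, spacing[0]);
      for (int z = 0; z < Z; ++z) g[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      R_xlen_t base = z + static_cast<R_xlen_t>(Z) * static_cast<R_xlen_t>(Y) * x;
      for (int y = 0; y < Y; ++y) f[y] = g[base + static_cast<R_xlen_t>(Z) * y];
      dt1d(f.data(), d.data(), v.data(), zb.data(), Y, spacing[1]);
      for (int y = 0; y < Y; ++y) g[base + static_cast<R_xlen_t>(Z) * y] = d[y];
    }
  // pass along x
  R_xlen_t strideX = static_cast<R_xlen_t>(Z) * Y;
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      R_xlen_t base = z + static_cast<R_xlen_t>(Z) * y;
      for (int x = 0; x < X; ++x) f[x] = g[base + strideX * x];
      dt1d(f.data(), d.data(), v.data(), zb.data(), X, spacing[2]);
      for (int x = 0; x < X; ++x) g[base + strideX * x] = d[x];
    }
  g.attr("dim") = dim;
  return g;
}

// ---------------------------------------------------------------------------
// im2col / col2im for the GEMM-based convolution path. Column j corresponds
// to output voxel j (same padding); row index is ci + Cin*(dz + kz*(dy +
// ky*dx)). col2im is the exact adjoint (scatter-add).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col(NumericVector x, int kz, int ky, int kx) {
  IntegerVector xd = dims_of(x);
  const int Cin = xd[0], Z = xd[1], Y = xd[2], X = xd[3];
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  const R_xlen_t N = static_cast<R_xlen_t>(Z) * Y * X;
  const int K = kz * ky * kx;
  NumericMatrix col(Cin * K, N);
  const double* xp = x.begin();
  double* cp = col.begin();
  const R_xlen_t nrow = static_cast<R_xlen_t>(Cin) * K;
  R_xlen_t j = 0;
  for (int ox = 0; ox < X; ++ox)
    for (int oy = 0; oy < Y; ++oy)
      for (int oz = 0; oz < Z; ++oz, ++j) {
        double* cj = cp + nrow * j;
        int r = 0;
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox + dx - px;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy + dy - py;
            for (int dz = 0; dz < kz; ++dz, r += Cin) {
              int iz = oz + dz - pz;
              if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z)
                continue;  // stays zero
              const double* xv = xp + static_cast<R_xlen_t>(Cin) *
                (iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix));
              for (int ci = 0; ci < Cin; ++ci) cj[r + ci] = xv[ci];
            }
          }
        }
      }
  return col;
}

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im(NumericMatrix col, IntegerVector xdim,
                     int kz, int ky, int kx) {
  const int Cin = xdim[0], Z = xdim[1], Y = xdim[2], X = xdim[3];
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  NumericVector gx(static_cast<R_xlen_t>(Cin) * Z * Y * X);
  gx.attr("dim") = xdim;
  const double* cp = col.begin();
  double* xp = gx.begin();
  const R_xlen_t nrow = col.nrow();
  R_xlen_t j = 0;
  for (int ox = 0; ox < X; ++ox)
    for (int oy = 0; oy < Y; ++oy)
      for (int oz = 0; oz < Z; ++oz, ++j) {
        const double* cj = cp + nrow * j;
        int r = 0;
        for (int dx = 0; dx < kx; ++dx) {
          int ix = ox + dx - px;
          for (int dy = 0; dy < ky; ++dy) {
            int iy = oy + dy - py;
            for (int dz = 0; dz < kz; ++dz, r += Cin) {
              int iz = oz + dz - pz;
              if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z)
                continue;
              double* xv = xp + static_cast<R_xlen_t>(Cin) *
                (iz + static_cast<R_xlen_t>(Z) * (iy + static_cast<R_xlen_t>(Y) * ix));
              for (int ci = 0; ci < Cin; ++ci) xv[ci] += cj[r + ci];
            }
          }
        }
      }
  return gx;
}
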
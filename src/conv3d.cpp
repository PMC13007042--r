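// 3D convolution primitives for the U-Net, via im2col + GEMM.
//
// Array conventions (match the R side):
//   feature maps: R arrays dim (nz, ny, nx, C), column-major, so z is the
//   fastest-varying index and channel the slowest.
//   conv weights: matrix (Kz*Ky*Kx*Cin) x Cout, rows ordered as an R array
//   dim (Kz, Ky, Kx, Cin) flattened column-major.
//   transposed-conv weights (kernel == stride): matrix (Sz*Sy*Sx*Cin) x Cout,
//   rows ordered as dim (Sz, Sy, Sx, Cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Build the im2col matrix: rows = output voxels (z fastest, then y, x),
// cols = (kz, ky, kx, cin) flattened with kz fastest.
static arma::mat im2col3d(const double* x, int nz, int ny, int nx, int cin,
                          int kz, int ky, int kx,
                          int sz, int sy, int sx,
                          int pz, int py, int px,
                          int oz, int oy, int ox) {
  const arma::uword n_out = (arma::uword)oz * oy * ox;
  arma::mat cols(n_out, (arma::uword)kz * ky * kx * cin, arma::fill::zeros);
  const arma::uword plane = (arma::uword)nz * ny;
  const arma::uword volsz = plane * nx;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (arma::uword)c * volsz;
    for (int dx = 0; dx < kx; ++dx) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dz = 0; dz < kz; ++dz) {
          arma::uword col = (arma::uword)dz + kz * ((arma::uword)dy + ky * ((arma::uword)dx + kx * (arma::uword)c));
          double* dst = cols.colptr(col);
          // valid output index ranges for this kernel offset (hoisted checks)
          int jz0 = std::max(0, (pz - dz + sz - 1) / sz), jz1 = std::min(oz, (nz + pz - dz + sz - 1) / sz);
          int jy0 = std::max(0, (py - dy + sy - 1) / sy), jy1 = std::min(oy, (ny + py - dy + sy - 1) / sy);
          int jx0 = std::max(0, (px - dx + sx - 1) / sx), jx1 = std::min(ox, (nx + px - dx + sx - 1) / sx);
          for (int jx = jx0; jx < jx1; ++jx) {
            int ix = jx * sx - px + dx;
            for (int jy = jy0; jy < jy1; ++jy) {
              int iy = jy * sy - py + dy;
              const double* src = xc + (arma::uword)ix * plane + (arma::uword)iy * nz - pz + dz;
              double* d = dst + ((arma::uword)jx * oy + jy) * oz;
              if (sz == 1) {
                for (int jz = jz0; jz < jz1; ++jz) d[jz] = src[jz];
              } else {
                for (int jz = jz0; jz < jz1; ++jz) d[jz] = src[(arma::uword)jz * sz];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the im2col layout back into an input-shaped gradient.
static void col2im3d(const arma::mat& cols, double* gx,
                     int nz, int ny, int nx, int cin,
                     int kz, int ky, int kx,
                     int sz, int sy, int sx,
                     int pz, int py, int px,
                     int oz, int oy, int ox) {
  const arma::uword plane = (arma::uword)nz * ny;
  const arma::uword volsz = plane * nx;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + (arma::uword)c * volsz;
    for (int dx = 0; dx < kx; ++dx) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dz = 0; dz < kz; ++dz) {
          arma::uword col = (arma::uword)dz + kz * ((arma::uword)dy + ky * ((arma::uword)dx + kx * (arma::uword)c));
          const double* src = cols.colptr(col);
          int jz0 = std::max(0, (pz - dz + sz - 1) / sz), jz1 = std::min(oz, (nz + pz - dz + sz - 1) / sz);
          int jy0 = std::max(0, (py - dy + sy - 1) / sy), jy1 = std::min(oy, (ny + py - dy + sy - 1) / sy);
          int jx0 = std::max(0, (px - dx + sx - 1) / sx), jx1 = std::min(ox, (nx + px - dx + sx - 1) / sx);
          for (int jx = jx0; jx < jx1; ++jx) {
            int ix = jx * sx - px + dx;
            for (int jy = jy0; jy < jy1; ++jy) {
              int iy = jy * sy - py + dy;
              double* d = gc + (arma::uword)ix * plane + (arma::uword)iy * nz - pz + dz;
              const double* sc = src + ((arma::uword)jx * oy + jy) * oz;
              if (sz == 1) {
                for (int jz = jz0; jz < jz1; ++jz) d[jz] += sc[jz];
              } else {
                for (int jz = jz0; jz < jz1; ++jz) d[(arma::uword)jz * sz] += sc[jz];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericMatrix w, NumericVector bias,
                             IntegerVector kdim, IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  int nz = xd[0], ny = xd[1], nx = xd[2], cin = xd[3];
  int kz = kdim[0], ky = kdim[1], kx = kdim[2];
  int sz = stride[0], sy = stride[1], sx = stride[2];
  int pz = pad[0], py = pad[1], px = pad[2];
  int cout = w.ncol();
  if ((int)w.nrow() != kz * ky * kx * cin)
    stop("weight rows (%d) do not match kernel*in_channels (%d)", w.nrow(), kz * ky * kx * cin);
  int oz = out_extent(nz, kz, sz, pz), oy = out_extent(ny, ky, sy, py), ox = out_extent(nx, kx, sx, px);
  if (oz < 1 || oy < 1 || ox < 1) stop("input smaller than kernel");

  arma::mat cols = im2col3d(x.begin(), nz, ny, nx, cin, kz, ky, kx, sz, sy, sx, pz, py, px, oz, oy, ox);
  arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), cout, false, true);
  arma::mat out = cols * wm;
  out.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), cout, false, true);

  NumericVector y(out.begin(), out.end());
  y.attr("dim") = IntegerVector::create(oz, oy, ox, cout);
  return y;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericMatrix w, NumericVector gy,
                     IntegerVector kdim, IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int nz = xd[0], ny = xd[1], nx = xd[2], cin = xd[3];
  int kz = kdim[0], ky = kdim[1], kx = kdim[2];
  int sz = stride[0], sy = stride[1], sx = stride[2];
  int pz = pad[0], py = pad[1], px = pad[2];
  int oz = gd[0], oy = gd[1], ox = gd[2], cout = gd[3];
  arma::uword n_out = (arma::uword)oz * oy * ox;

  arma::mat cols = im2col3d(x.begin(), nz, ny, nx, cin, kz, ky, kx, sz, sy, sx, pz, py, px, oz, oy, ox);
  arma::mat gym(const_cast<double*>(gy.begin()), n_out, cout, false, true);
  arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), cout, false, true);

  arma::mat gw = cols.t() * gym;                    // (K*Cin) x Cout
  arma::rowvec gb = arma::sum(gym, 0);              // Cout
  arma::mat gcols = gym * wm.t();                   // n_out x (K*Cin)

  NumericVector gx((arma::uword)nz * ny * nx * cin);
  col2im3d(gcols, gx.begin(), nz, ny, nx, cin, kz, ky, kx, sz, sy, sx, pz, py, px, oz, oy, ox);
  gx.attr("dim") = IntegerVector::create(nz, ny, nx, cin);

  NumericMatrix gwr(gw.n_rows, gw.n_cols, gw.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed conv with kernel == stride (non-overlapping learned upsampling):
// y[z*sz+dz, y*sy+dy, x*sx+dx, c2] = sum_c1 W[dz,dy,dx,c1,c2] * x[z,y,x,c1] + b[c2]
// [[Rcpp::export(name = ".convtr3d_forward")]]
NumericVector convtr3d_forward(NumericVector x, NumericMatrix w, NumericVector bias,
                               IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  int nz = xd[0], ny = xd[1], nx = xd[2], cin = xd[3];
  int sz = stride[0], sy = stride[1], sx = stride[2];
  int cout = w.ncol();
  int oz = nz * sz, oy = ny * sy, ox = nx * sx;
  arma::uword n_in = (arma::uword)nz * ny * nx;

  // x as matrix n_in x cin
  arma::mat xm(const_cast<double*>(x.begin()), n_in, cin, false, true);
  NumericVector y((arma::uword)oz * oy * ox * cout);
  const arma::uword oplane = (arma::uword)oz * oy;
  const arma::uword ovol = oplane * ox;

  for (int dx = 0; dx < sx; ++dx)
    for (int dy = 0; dy < sy; ++dy)
      for (int dz = 0; dz < sz; ++dz) {
        // weight slice for this offset: cin x cout
        arma::mat ws(cin, cout);
        for (int c1 = 0; c1 < cin; ++c1) {
          arma::uword row = (arma::uword)dz + sz * ((arma::uword)dy + sy * ((arma::uword)dx + sx * (arma::uword)c1));
          for (int c2 = 0; c2 < cout; ++c2) ws(c1, c2) = w(row, c2);
        }
        arma::mat yo = xm * ws;  // n_in x cout
        for (int c2 = 0; c2 < cout; ++c2) {
          double* yc = y.begin() + (arma::uword)c2 * ovol;
          const double* src = yo.colptr(c2);
          for (int jx = 0; jx < nx; ++jx)
            for (int jy = 0; jy < ny; ++jy) {
              arma::uword src_base = ((arma::uword)jx * ny + jy) * nz;
              arma::uword dst_base = (arma::uword)(jx * sx + dx) * oplane + (arma::uword)(jy * sy + dy) * oz + dz;
              for (int jz = 0; jz < nz; ++jz)
                yc[dst_base + (arma::uword)jz * sz] = src[src_base + jz];
            }
        }
      }
  // bias
  for (int c2 = 0; c2 < cout; ++c2) {
    double* yc = y.begin() + (arma::uword)c2 * ovol;
    double b = bias[c2];
    for (arma::uword i = 0; i < ovol; ++i) yc[i] += b;
  }
  y.attr("dim") = IntegerVector::create(oz, oy, ox, cout);
  return y;
}

// [[Rcpp::export(name = ".convtr3d_backward")]]
List convtr3d_backward(NumericVector x, NumericMatrix w, NumericVector gy,
                       IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int nz = xd[0], ny = xd[1], nx = xd[2], cin = xd[3];
  int sz = stride[0], sy = stride[1], sx = stride[2];
  int oz = gd[0], oy = gd[1], ox = gd[2];
  int cout = gd[3];
  arma::uword n_in = (arma::uword)nz * ny * nx;
  const arma::uword oplane = (arma::uword)oz * oy;
  const arma::uword ovol = oplane * ox;

  arma::mat xm(const_cast<double*>(x.begin()), n_in, cin, false, true);
  arma::mat gxm(n_in, cin, arma::fill::zeros);
  NumericMatrix gw(w.nrow(), w.ncol());
  NumericVector gb(cout);

  for (int dx = 0; dx < sx; ++dx)
    for (int dy = 0; dy < sy; ++dy)
      for (int dz = 0; dz < sz; ++dz) {
        // gather gy at this offset: n_in x cout
        arma::mat gyo(n_in, cout);
        for (int c2 = 0; c2 < cout; ++c2) {
          const double* gc = gy.begin() + (arma::uword)c2 * ovol;
          double* dst = gyo.colptr(c2);
          for (int jx = 0; jx < nx; ++jx)
            for (int jy = 0; jy < ny; ++jy) {
              arma::uword dst_base = ((arma::uword)jx * ny + jy) * nz;
              arma::uword src_base = (arma::uword)(jx * sx + dx) * oplane + (arma::uword)(jy * sy + dy) * oz + dz;
              for (int jz = 0; jz < nz; ++jz)
                dst[dst_base + jz] = gc[src_base + (arma::uword)jz * sz];
            }
        }
        arma::mat ws(cin, cout);
        for (int c1 = 0; c1 < cin; ++c1) {
          arma::uword row = (arma::uword)dz + sz * ((arma::uword)dy + sy * ((arma::uword)dx + sx * (arma::uword)c1));
          for (int c2 = 0; c2 < cout; ++c2) ws(c1, c2) = w(row, c2);
        }
        gxm += gyo * ws.t();
        arma::mat gws = xm.t() * gyo;  // cin x cout
        for (int c1 = 0; c1 < cin; ++c1) {
          arma::uword row = (arma::uword)dz + sz * ((arma::uword)dy + sy * ((arma::uword)dx + sx * (arma::uword)c1));
          for (int c2 = 0; c2 < cout; ++c2) gw(row, c2) += gws(c1, c2);
        }
        for (int c2 = 0; c2 < cout; ++c2) gb[c2] += arma::accu(gyo.col(c2));
      }

  NumericVector gx(gxm.begin(), gxm.end());
  gx.attr("dim") = IntegerVector::create(nz, ny, nx, cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Fused instance-norm + leaky-ReLU forward: per-channel normalization over
// the spatial grid of one sample, affine (gamma, beta), slope-0.01 leak.
// Returns the activation, the normalized tensor and inverse stddevs (the
// backward pass needs both).
// [[Rcpp::export(name = ".in_lrelu_forward")]]
List in_lrelu_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                      double slope, double eps) {
  IntegerVector d = x.attr("dim");
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  int nc = d[3];
  NumericVector y(n * nc), xhat(n * nc), inv_std(nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + n * c;
    double* yc = y.begin() + n * c;
    double* hc = xhat.begin() + n * c;
    double mu = 0;
    for (R_xlen_t i = 0; i < n; ++i) mu += xc[i];
    mu /= n;
    double v = 0;
    for (R_xlen_t i = 0; i < n; ++i) { double dlt = xc[i] - mu; v += dlt * dlt; }
    v /= n;
    double is = 1.0 / std::sqrt(v + eps);
    inv_std[c] = is;
    double g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < n; ++i) {
      double h = (xc[i] - mu) * is;
      hc[i] = h;
      double a = g * h + b;
      yc[i] = a >= 0 ? a : slope * a;
    }
  }
  y.attr("dim") = d;
  xhat.attr("dim") = d;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_std"] = inv_std);
}

// Fused backward: gy is the gradient at the activation output; `y` the
// forward activation (its sign encodes the leak mask).
// [[Rcpp::export(name = ".in_lrelu_backward")]]
List in_lrelu_backward(NumericVector gy, NumericVector y, NumericVector xhat,
                       NumericVector inv_std, NumericVector gamma, double slope) {
  IntegerVector d = gy.attr("dim");
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  int nc = d[3];
  NumericVector gx(n * nc), ggamma(nc), gbeta(nc);
  for (int c = 0; c < nc; ++c) {
    const double* gyc = gy.begin() + n * c;
    const double* yc = y.begin() + n * c;
    const double* hc = xhat.begin() + n * c;
    double* gxc = gx.begin() + n * c;
    double g = gamma[c], is = inv_std[c];
    double s1 = 0, s2 = 0, gg = 0, gb = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double ga = yc[i] < 0 ? gyc[i] * slope : gyc[i];  // through the leak
      gg += ga * hc[i];
      gb += ga;
      double dh = ga * g;
      s1 += dh;
      s2 += dh * hc[i];
      gxc[i] = dh;  // temporarily store dxhat
    }
    ggamma[c] = gg; gbeta[c] = gb;
    double invn = 1.0 / n;
    for (R_xlen_t i = 0; i < n; ++i)
      gxc[i] = is * (gxc[i] - invn * s1 - hc[i] * invn * s2);
  }
  gx.attr("dim") = d;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
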
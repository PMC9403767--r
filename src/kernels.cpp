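// Low-level kernels: connected components, resampling, surface distances,
// separable blur, and conv/pool forward+backward for the network engine.
// Arrays are R column-major with dims (nz, ny, nx [, c]); flat index
// z + nz*(y + ny*(x + nx*c)).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  if (connectivity == 6) {
    offs = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) offs.push_back({{dz, dy, dx}});
  }
  int cur = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (mask[i] == 0 || labels[i] != 0) continue;
        ++cur;
        labels[i] = cur;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int j = stack.back();
          stack.pop_back();
          int jz = j % nz, jy = (j / nz) % ny, jx = j / (nz * ny);
          for (const auto &o : offs) {
            int z2 = jz + o[0], y2 = jy + o[1], x2 = jx + o[2];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            int k = idx3(z2, y2, x2, nz, ny);
            if (mask[k] != 0 && labels[k] == 0) {
              labels[k] = cur;
              stack.push_back(k);
            }
          }
        }
      }
  labels.attr("n_components") = cur;
  return labels;
}

// Trilinear / nearest resampling. Voxel i (0-based) sits at physical i*spacing
// relative to a shared origin, so identical spacing reproduces the input.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector in_dims,
                             NumericVector in_sp, IntegerVector out_dims,
                             NumericVector out_sp, bool nearest) {
  int nz = in_dims[0], ny = in_dims[1], nx = in_dims[2];
  int oz = out_dims[0], oy = out_dims[1], ox = out_dims[2];
  NumericVector out(static_cast<R_xlen_t>(oz) * oy * ox);
  for (int c = 0; c < ox; ++c)
    for (int b = 0; b < oy; ++b)
      for (int a = 0; a < oz; ++a) {
        double fz = a * out_sp[0] / in_sp[0];
        double fy = b * out_sp[1] / in_sp[1];
        double fx = c * out_sp[2] / in_sp[2];
        fz = std::min(std::max(fz, 0.0), static_cast<double>(nz - 1));
        fy = std::min(std::max(fy, 0.0), static_cast<double>(ny - 1));
        fx = std::min(std::max(fx, 0.0), static_cast<double>(nx - 1));
        double v;
        if (nearest) {
          v = x[idx3((int)std::lround(fz), (int)std::lround(fy),
                     (int)std::lround(fx), nz, ny)];
        } else {
          int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy),
              x0 = (int)std::floor(fx);
          int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
              x1 = std::min(x0 + 1, nx - 1);
          double wz = fz - z0, wy = fy - y0, wx = fx - x0;
          double c00 = x[idx3(z0, y0, x0, nz, ny)] * (1 - wz) +
                       x[idx3(z1, y0, x0, nz, ny)] * wz;
          double c01 = x[idx3(z0, y0, x1, nz, ny)] * (1 - wz) +
                       x[idx3(z1, y0, x1, nz, ny)] * wz;
          double c10 = x[idx3(z0, y1, x0, nz, ny)] * (1 - wz) +
                       x[idx3(z1, y1, x0, nz, ny)] * wz;
          double c11 = x[idx3(z0, y1, x1, nz, ny)] * (1 - wz) +
                       x[idx3(z1, y1, x1, nz, ny)] * wz;
          double c0 = c00 * (1 - wy) + c10 * wy;
          double c1 = c01 * (1 - wy) + c11 * wy;
          v = c0 * (1 - wx) + c1 * wx;
        }
        out[idx3(a, b, c, oz, oy)] = v;
      }
  return out;
}

// Surface voxels: foreground with >=1 face-adjacent background (out-of-bounds
// counts as background). Returns 0-based flat indices.
// [[Rcpp::export]]
IntegerVector cpp_surface_voxels(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (mask[i] == 0) continue;
        bool surf = z == 0 || z == nz - 1 || y == 0 || y == ny - 1 ||
                    x == 0 || x == nx - 1;
        if (!surf) {
          surf = mask[idx3(z - 1, y, x, nz, ny)] == 0 ||
                 mask[idx3(z + 1, y, x, nz, ny)] == 0 ||
                 mask[idx3(z, y - 1, x, nz, ny)] == 0 ||
                 mask[idx3(z, y + 1, x, nz, ny)] == 0 ||
                 mask[idx3(z, y, x - 1, nz, ny)] == 0 ||
                 mask[idx3(z, y, x + 1, nz, ny)] == 0;
        }
        if (surf) out.push_back(i);
      }
  return wrap(out);
}

// Nearest-surface distances from each point of A to the point set B, in mm.
// [[Rcpp::export]]
NumericVector cpp_nearest_distances(IntegerVector a_idx, IntegerVector b_idx,
                                    IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1];
  int na = a_idx.size(), nb = b_idx.size();
  std::vector<double> bz(nb), by(nb), bx(nb);
  for (int j = 0; j < nb; ++j) {
    int i = b_idx[j];
    bz[j] = (i % nz) * spacing[0];
    by[j] = ((i / nz) % ny) * spacing[1];
    bx[j] = (i / (nz * ny)) * spacing[2];
  }
  NumericVector out(na);
  for (int k = 0; k < na; ++k) {
    int i = a_idx[k];
    double az = (i % nz) * spacing[0];
    double ay = ((i / nz) % ny) * spacing[1];
    double ax = (i / (nz * ny)) * spacing[2];
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dz = az - bz[j], dy = ay - by[j], dx = ax - bx[j];
      double d = dz * dz + dy * dy + dx * dx;
      if (d < best) best = d;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}

// Separable 1-D convolution along one axis (0=z,1=y,2=x), zero-padded.
// [[Rcpp::export]]
NumericVector cpp_blur1d(NumericVector x, IntegerVector dims, int axis,
                         NumericVector kernel) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int kn = kernel.size(), kh = kn / 2;
  NumericVector out(x.size());
  for (int c = 0; c < nx; ++c)
    for (int b = 0; b < ny; ++b)
      for (int a = 0; a < nz; ++a) {
        double s = 0.0;
        for (int k = 0; k < kn; ++k) {
          int off = k - kh;
          int z = a, y = b, xx = c;
          if (axis == 0) z += off;
          else if (axis == 1) y += off;
          else xx += off;
          if (z < 0 || z >= nz || y < 0 || y >= ny || xx < 0 || xx >= nx)
            continue;
          s += kernel[k] * x[idx3(z, y, xx, nz, ny)];
        }
        out[idx3(a, b, c, nz, ny)] = s;
      }
  return out;
}

// ---- convolution engine -----------------------------------------------------
// Input x: (nz, ny, nx, cin); weights: K x cout matrix with row ordering
// kz fastest, then ky, kx, then cin. "Same"-style zero padding for the given
// per-axis stride: out = ceil(n / stride).

static void conv_geometry(const IntegerVector &xd, const IntegerVector &kern,
                          const IntegerVector &stride, int *od, int *plo) {
  for (int a = 0; a < 3; ++a) {
    od[a] = (xd[a] + stride[a] - 1) / stride[a];
    int pad = std::max((od[a] - 1) * stride[a] + kern[a] - xd[a], 0);
    plo[a] = pad / 2;
  }
}

// fill columns [m0, m0+len) of the im2col matrix into `chunk` (K x len)
static void im2col_chunk(const double *x, const IntegerVector &xd,
                         const IntegerVector &kern,
                         const IntegerVector &stride, const int *od,
                         const int *plo, long m0, long len,
                         arma::mat &chunk) {
  int nz = xd[0], ny = xd[1], nx = xd[2], cin = xd[3];
  int kz = kern[0], ky = kern[1], kx = kern[2];
  for (long q = 0; q < len; ++q) {
    long m = m0 + q;
    int oz = m % od[0];
    int oy = (m / od[0]) % od[1];
    int ox = m / (static_cast<long>(od[0]) * od[1]);
    int z0 = oz * stride[0] - plo[0];
    int y0 = oy * stride[1] - plo[1];
    int x0 = ox * stride[2] - plo[2];
    double *col = chunk.colptr(q);
    bool boundary = z0 < 0 || z0 + kz > nz || y0 < 0 || y0 + ky > ny ||
                    x0 < 0 || x0 + kx > nx;
    if (boundary)
      std::fill(col, col + static_cast<long>(kz) * ky * kx * cin, 0.0);
    for (int c = 0; c < cin; ++c) {
      long cbase = static_cast<long>(nz) * ny * nx * c;
      for (int jx = 0; jx < kx; ++jx) {
        int xx = x0 + jx;
        if (xx < 0 || xx >= nx) continue;
        for (int jy = 0; jy < ky; ++jy) {
          int yy = y0 + jy;
          if (yy < 0 || yy >= ny) continue;
          int jzlo = std::max(0, -z0), jzhi = std::min(kz, nz - z0);
          const double *src = x + cbase + idx3(z0 + jzlo, yy, xx, nz, ny);
          double *dst = col + kz * (jy + ky * (jx + kx * c)) + jzlo;
          for (int jz = jzlo; jz < jzhi; ++jz) *dst++ = *src++;
        }
      }
    }
  }
}

static const long CONV_CHUNK = 8192;
static const int KBLOCK = 192;

// Stride-1 fast path: build blocks of the (voxels x K) shifted-input matrix
// with contiguous z-run copies. Row ordering of the weight matrix is
// unchanged (kz fastest, then ky, kx, cin).
static void fill_shift_block(const double *x, int nz, int ny, int nx,
                             const IntegerVector &kern, const int *plo,
                             int r0, int rb, arma::mat &B) {
  int kz = kern[0], ky = kern[1], kx = kern[2];
  long plane = static_cast<long>(nz) * ny;
  for (int j = 0; j < rb; ++j) {
    int r = r0 + j;
    int jz = r % kz, jy = (r / kz) % ky, jx = (r / (kz * ky)) % kx;
    int c = r / (kz * ky * kx);
    int dz = jz - plo[0], dy = jy - plo[1], dx = jx - plo[2];
    long cbase = plane * nx * c;
    double *col = B.colptr(j);
    int lo = std::max(0, -dz), hi = std::min(nz, nz - dz);
    for (int ox = 0; ox < nx; ++ox) {
      int sx = ox + dx;
      if (sx < 0 || sx >= nx) {
        std::fill(col + plane * ox, col + plane * (ox + 1), 0.0);
        continue;
      }
      for (int oy = 0; oy < ny; ++oy) {
        int sy = oy + dy;
        double *dst = col + plane * ox + static_cast<long>(nz) * oy;
        if (sy < 0 || sy >= ny) {
          std::fill(dst, dst + nz, 0.0);
          continue;
        }
        const double *src = x + cbase + plane * sx +
                            static_cast<long>(nz) * sy;
        if (lo > 0) std::fill(dst, dst + lo, 0.0);
        std::copy(src + lo + dz, src + hi + dz, dst + lo);
        if (hi < nz) std::fill(dst + hi, dst + nz, 0.0);
      }
    }
  }
}

// adjoint: scatter-add the block columns back into dx
static void scatter_shift_block(double *dx, int nz, int ny, int nx,
                                const IntegerVector &kern, const int *plo,
                                int r0, int rb, const arma::mat &B) {
  int kz = kern[0], ky = kern[1], kx = kern[2];
  long plane = static_cast<long>(nz) * ny;
  for (int j = 0; j < rb; ++j) {
    int r = r0 + j;
    int jz = r % kz, jy = (r / kz) % ky, jx = (r / (kz * ky)) % kx;
    int c = r / (kz * ky * kx);
    int dz = jz - plo[0], dy = jy - plo[1], dx_ = jx - plo[2];
    long cbase = plane * nx * c;
    const double *col = B.colptr(j);
    int lo = std::max(0, -dz), hi = std::min(nz, nz - dz);
    for (int ox = 0; ox < nx; ++ox) {
      int sx = ox + dx_;
      if (sx < 0 || sx >= nx) continue;
      for (int oy = 0; oy < ny; ++oy) {
        int sy = oy + dy;
        if (sy < 0 || sy >= ny) continue;
        const double *gsrc = col + plane * ox + static_cast<long>(nz) * oy;
        double *acc = dx + cbase + plane * sx + static_cast<long>(nz) * sy +
                      dz;
        for (int oz = lo; oz < hi; ++oz) acc[oz] += gsrc[oz];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdims,
                            NumericMatrix w, NumericVector bias,
                            IntegerVector kern, IntegerVector stride) {
  int od[3], plo[3];
  conv_geometry(xdims, kern, stride, od, plo);
  int cout = w.ncol(), cin = xdims[3];
  long M = static_cast<long>(od[0]) * od[1] * od[2];
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector res(M * cout);
  arma::mat out(res.begin(), M, cout, false, true);  // M x cout view
  bool k1 = kern[0] == 1 && kern[1] == 1 && kern[2] == 1 &&
            stride[0] == 1 && stride[1] == 1 && stride[2] == 1;
  bool s1 = stride[0] == 1 && stride[1] == 1 && stride[2] == 1;
  if (k1) {  // 1x1x1: plain GEMM on the (voxels x channels) view
    arma::mat X(x.begin(), M, cin, false);
    out = X * W;
  } else if (s1) {
    int K = w.nrow();
    int nz = xdims[0], ny = xdims[1], nx = xdims[2];
    arma::mat B(M, std::min<long>(K, KBLOCK));
    out.zeros();
    for (int r0 = 0; r0 < K; r0 += KBLOCK) {
      int rb = std::min<int>(KBLOCK, K - r0);
      fill_shift_block(x.begin(), nz, ny, nx, kern, plo, r0, rb, B);
      out += B.cols(0, rb - 1) * W.rows(r0, r0 + rb - 1);
    }
  } else {
    long chunk_len = std::min(M, CONV_CHUNK);
    arma::mat chunk(w.nrow(), chunk_len);
    for (long m0 = 0; m0 < M; m0 += chunk_len) {
      long len = std::min(chunk_len, M - m0);
      im2col_chunk(x.begin(), xdims, kern, stride, od, plo, m0, len, chunk);
      out.rows(m0, m0 + len - 1) =
          chunk.cols(0, len - 1).t() * W;
    }
  }
  if (bias.size() == (R_xlen_t)cout)
    out.each_row() += arma::rowvec(bias.begin(), cout, false);
  res.attr("dim") = IntegerVector::create(od[0], od[1], od[2], cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdims, NumericMatrix w,
                   NumericVector dout, IntegerVector kern,
                   IntegerVector stride, bool need_dx) {
  int od[3], plo[3];
  conv_geometry(xdims, kern, stride, od, plo);
  int nz = xdims[0], ny = xdims[1], nx = xdims[2], cin = xdims[3];
  int kz = kern[0], ky = kern[1], kx = kern[2];
  int cout = w.ncol();
  long M = static_cast<long>(od[0]) * od[1] * od[2];
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dOut(dout.begin(), M, cout, false);  // M x cout
  arma::vec db = arma::sum(dOut, 0).t();
  bool k1 = kern[0] == 1 && kern[1] == 1 && kern[2] == 1 &&
            stride[0] == 1 && stride[1] == 1 && stride[2] == 1;
  if (k1) {
    arma::mat X(x.begin(), M, cin, false);
    arma::mat dW = X.t() * dOut;
    NumericVector dx;
    if (need_dx) {
      dx = NumericVector(x.size());
      arma::mat dX(dx.begin(), M, cin, false, true);
      dX = dOut * W.t();
      dx.attr("dim") = xdims;
    }
    return List::create(_["dw"] = wrap(dW), _["db"] = wrap(db),
                        _["dx"] = dx);
  }
  arma::mat dW(w.nrow(), cout, arma::fill::zeros);
  NumericVector dx;
  double *dxp = nullptr;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xdims;
    dxp = dx.begin();
  }
  bool s1 = stride[0] == 1 && stride[1] == 1 && stride[2] == 1;
  if (s1) {
    int K = w.nrow();
    arma::mat B(M, std::min<long>(K, KBLOCK));
    for (int r0 = 0; r0 < K; r0 += KBLOCK) {
      int rb = std::min<int>(KBLOCK, K - r0);
      fill_shift_block(x.begin(), nz, ny, nx, kern, plo, r0, rb, B);
      dW.rows(r0, r0 + rb - 1) = B.cols(0, rb - 1).t() * dOut;
      if (need_dx) {
        arma::mat dB = dOut * W.rows(r0, r0 + rb - 1).t();
        scatter_shift_block(dxp, nz, ny, nx, kern, plo, r0, rb, dB);
      }
    }
    return List::create(_["dw"] = wrap(dW), _["db"] = wrap(db),
                        _["dx"] = dx);
  }
  long chunk_len = std::min(M, CONV_CHUNK);
  arma::mat chunk(w.nrow(), chunk_len);
  arma::mat dCols(w.nrow(), chunk_len);
  for (long m0 = 0; m0 < M; m0 += chunk_len) {
    long len = std::min(chunk_len, M - m0);
    im2col_chunk(x.begin(), xdims, kern, stride, od, plo, m0, len, chunk);
    dW += chunk.cols(0, len - 1) * dOut.rows(m0, m0 + len - 1);
    if (need_dx) {
      dCols.cols(0, len - 1) = W * dOut.rows(m0, m0 + len - 1).t();
      for (long q = 0; q < len; ++q) {
        long m = m0 + q;
        int oz = m % od[0];
        int oy = (m / od[0]) % od[1];
        int ox = m / (static_cast<long>(od[0]) * od[1]);
        int z0 = oz * stride[0] - plo[0];
        int y0 = oy * stride[1] - plo[1];
        int x0 = ox * stride[2] - plo[2];
        double *col = dCols.colptr(q);
        for (int c = 0; c < cin; ++c) {
          long cbase = static_cast<long>(nz) * ny * nx * c;
          for (int jx = 0; jx < kx; ++jx) {
            int xx = x0 + jx;
            if (xx < 0 || xx >= nx) continue;
            for (int jy = 0; jy < ky; ++jy) {
              int yy = y0 + jy;
              if (yy < 0 || yy >= ny) continue;
              double *dst = dxp + cbase + idx3(z0, yy, xx, nz, ny);
              double *src = col + kz * (jy + ky * (jx + kx * c));
              int jzlo = std::max(0, -z0), jzhi = std::min(kz, nz - z0);
              for (int jz = jzlo; jz < jzhi; ++jz) dst[jz] += src[jz];
            }
          }
        }
      }
    }
  }
  return List::create(_["dw"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}

// Max pooling with per-axis integer factors; input dims must be divisible.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdims, IntegerVector f) {
  int nz = xdims[0], ny = xdims[1], nx = xdims[2], nc = xdims[3];
  int oz = nz / f[0], oy = ny / f[1], ox = nx / f[2];
  long N = static_cast<long>(oz) * oy * ox * nc;
  NumericVector out(N);
  IntegerVector arg(N);
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long cbase = static_cast<long>(nz) * ny * nx * c;
    for (int b = 0; b < ox; ++b)
      for (int a = 0; a < oy; ++a)
        for (int d = 0; d < oz; ++d, ++o) {
          double best = R_NegInf;
          long bi = -1;
          for (int jx = 0; jx < f[2]; ++jx)
            for (int jy = 0; jy < f[1]; ++jy)
              for (int jz = 0; jz < f[0]; ++jz) {
                long i = cbase + idx3(d * f[0] + jz, a * f[1] + jy,
                                      b * f[2] + jx, nz, ny);
                if (x[i] > best) { best = x[i]; bi = i; }
              }
          out[o] = best;
          arg[o] = bi;
        }
  }
  out.attr("dim") = IntegerVector::create(oz, oy, ox, nc);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dout, IntegerVector argmax,
                             IntegerVector xdims) {
  NumericVector dx(static_cast<R_xlen_t>(xdims[0]) * xdims[1] * xdims[2] *
                   xdims[3]);
  for (R_xlen_t o = 0; o < dout.size(); ++o) dx[argmax[o]] += dout[o];
  dx.attr("dim") = xdims;
  return dx;
}

// Average pooling (used by DenseNet-style transition layers).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(NumericVector x, IntegerVector xdims,
                             IntegerVector f) {
  int nz = xdims[0], ny = xdims[1], nx = xdims[2], nc = xdims[3];
  int oz = nz / f[0], oy = ny / f[1], ox = nx / f[2];
  double w = 1.0 / (f[0] * f[1] * f[2]);
  NumericVector out(static_cast<R_xlen_t>(oz) * oy * ox * nc);
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long cbase = static_cast<long>(nz) * ny * nx * c;
    for (int b = 0; b < ox; ++b)
      for (int a = 0; a < oy; ++a)
        for (int d = 0; d < oz; ++d, ++o) {
          double s = 0;
          for (int jx = 0; jx < f[2]; ++jx)
            for (int jy = 0; jy < f[1]; ++jy)
              for (int jz = 0; jz < f[0]; ++jz)
                s += x[cbase + idx3(d * f[0] + jz, a * f[1] + jy,
                                    b * f[2] + jx, nz, ny)];
          out[o] = s * w;
        }
  }
  out.attr("dim") = IntegerVector::create(oz, oy, ox, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(NumericVector dout, IntegerVector xdims,
                             IntegerVector f) {
  int nz = xdims[0], ny = xdims[1], nx = xdims[2], nc = xdims[3];
  int oz = nz / f[0], oy = ny / f[1], ox = nx / f[2];
  double w = 1.0 / (f[0] * f[1] * f[2]);
  NumericVector dx(static_cast<R_xlen_t>(nz) * ny * nx * nc);
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    long cbase = static_cast<long>(nz) * ny * nx * c;
    for (int b = 0; b < ox; ++b)
      for (int a = 0; a < oy; ++a)
        for (int d = 0; d < oz; ++d, ++o) {
          double g = dout[o] * w;
          for (int jx = 0; jx < f[2]; ++jx)
            for (int jy = 0; jy < f[1]; ++jy)
              for (int jz = 0; jz < f[0]; ++jz)
                dx[cbase + idx3(d * f[0] + jz, a * f[1] + jy, b * f[2] + jx,
                                nz, ny)] += g;
        }
  }
  dx.attr("dim") = xdims;
  return dx;
}
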
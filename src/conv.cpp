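// Convolution kernels used by the registration and synthesis networks.
// Layout conventions (R column-major, fastest index first):
//   3D tensors: [nz, ny, nx, C]
//   2D batched tensors: [ny, nx, C, N]
// Weights: 3D [k, k, k, Cin, Cout]; 2D [k, k, Cin, Cout].
// Zero padding. GEMM runs in single precision; the im2col buffer is stored
// transposed (N x R) so both its fill and the output copy are contiguous.
// Forward and backward both rebuild the buffer, so no large caches cross
// the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// ---------- 3D ----------

// colsT: N x R with N = oz*oy*ox, R = k^3*ci; column r = (kz,ky,kx,c).
static void im2col3d(const double* x, int nz, int ny, int nx, int ci,
                     int k, int stride, int pad,
                     int oz, int oy, int ox, arma::fmat& colsT) {
  const int k3 = k * k * k;
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (long)c * nz * ny * nx;
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          int r = kz + k * (ky + k * kx) + k3 * c;
          float* col = colsT.colptr(r);
          long j = 0;
          for (int xi = 0; xi < ox; ++xi) {
            int xx = xi * stride - pad + kx;
            bool xok = xx >= 0 && xx < nx;
            for (int yi = 0; yi < oy; ++yi) {
              int yy = yi * stride - pad + ky;
              bool yok = yy >= 0 && yy < ny;
              if (!xok || !yok) {
                for (int zi = 0; zi < oz; ++zi) col[j++] = 0.0f;
              } else {
                const double* base = xc + (long)nz * (yy + (long)ny * xx);
                for (int zi = 0; zi < oz; ++zi) {
                  int zz = zi * stride - pad + kz;
                  col[j++] = (zz >= 0 && zz < nz) ? (float)base[zz] : 0.0f;
                }
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, int k, int co,
                                 NumericVector b, int stride, int pad) {
  int nz = xdim[0], ny = xdim[1], nx = xdim[2], ci = xdim[3];
  int oz = out_dim(nz, k, stride, pad);
  int oy = out_dim(ny, k, stride, pad);
  int ox = out_dim(nx, k, stride, pad);
  const int k3 = k * k * k, R = k3 * ci;
  const long N = (long)oz * oy * ox;

  arma::fmat colsT(N, R);
  im2col3d(x.begin(), nz, ny, nx, ci, k, stride, pad, oz, oy, ox, colsT);

  arma::fmat Wt(R, co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) Wt(r, o) = (float)w[r + (long)R * o];

  arma::fmat Yt = colsT * Wt;  // N x co
  NumericVector y((long)N * co);
  for (int o = 0; o < co; ++o) {
    double bo = b[o];
    const float* yo = Yt.colptr(o);
    for (long j = 0; j < N; ++j) y[j + N * o] = yo[j] + bo;
  }
  y.attr("dim") = IntegerVector::create(oz, oy, ox, co);
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, int k, int co,
                         int stride, int pad, NumericVector dy) {
  int nz = xdim[0], ny = xdim[1], nx = xdim[2], ci = xdim[3];
  int oz = out_dim(nz, k, stride, pad);
  int oy = out_dim(ny, k, stride, pad);
  int ox = out_dim(nx, k, stride, pad);
  const int k3 = k * k * k, R = k3 * ci;
  const long N = (long)oz * oy * ox;

  arma::fmat colsT(N, R);
  im2col3d(x.begin(), nz, ny, nx, ci, k, stride, pad, oz, oy, ox, colsT);

  arma::fmat D(N, co);
  NumericVector dbv(co);
  for (int o = 0; o < co; ++o) {
    float* dcol = D.colptr(o);
    double acc = 0;
    const double* dsrc = dy.begin() + N * o;
    for (long j = 0; j < N; ++j) { dcol[j] = (float)dsrc[j]; acc += dsrc[j]; }
    dbv[o] = acc;
  }

  arma::fmat dW = colsT.t() * D;     // R x co (transposed weight grad)
  arma::fmat Wt(R, co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) Wt(r, o) = (float)w[r + (long)R * o];
  arma::fmat dcolsT = D * Wt.t();    // N x R

  NumericVector dx((long)nz * ny * nx * ci);
  double* dxp = dx.begin();
  for (int c = 0; c < ci; ++c) {
    double* dxc = dxp + (long)c * nz * ny * nx;
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          int r = kz + k * (ky + k * kx) + k3 * c;
          const float* col = dcolsT.colptr(r);
          long j = 0;
          for (int xi = 0; xi < ox; ++xi) {
            int xx = xi * stride - pad + kx;
            bool xok = xx >= 0 && xx < nx;
            for (int yi = 0; yi < oy; ++yi) {
              int yy = yi * stride - pad + ky;
              if (!xok || yy < 0 || yy >= ny) { j += oz; continue; }
              double* base = dxc + (long)nz * (yy + (long)ny * xx);
              for (int zi = 0; zi < oz; ++zi) {
                int zz = zi * stride - pad + kz;
                if (zz >= 0 && zz < nz) base[zz] += col[j];
                ++j;
              }
            }
          }
        }
  }
  dx.attr("dim") = IntegerVector::create(nz, ny, nx, ci);

  NumericVector dwv((long)R * co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) dwv[r + (long)R * o] = dW(r, o);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// ---------- 2D (batched) ----------

// colsT: N x R with N = oy*ox*nb, R = k^2*ci; column r = (ky,kx,c).
static void im2col2d(const double* x, int ny, int nx, int ci, int nb,
                     int k, int stride, int pad,
                     int oy, int ox, arma::fmat& colsT) {
  const int k2 = k * k;
  const long S = (long)oy * ox;
  for (int c = 0; c < ci; ++c)
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        int r = ky + k * kx + k2 * c;
        float* col = colsT.colptr(r);
        for (int bI = 0; bI < nb; ++bI) {
          const double* xc = x + (long)bI * ny * nx * ci + (long)c * ny * nx;
          long j = S * bI;
          for (int xi = 0; xi < ox; ++xi) {
            int xx = xi * stride - pad + kx;
            bool xok = xx >= 0 && xx < nx;
            if (!xok) {
              for (int yi = 0; yi < oy; ++yi) col[j++] = 0.0f;
              continue;
            }
            const double* base = xc + (long)ny * xx;
            for (int yi = 0; yi < oy; ++yi) {
              int yy = yi * stride - pad + ky;
              col[j++] = (yy >= 0 && yy < ny) ? (float)base[yy] : 0.0f;
            }
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, int k, int co,
                                 NumericVector b, int stride, int pad) {
  int ny = xdim[0], nx = xdim[1], ci = xdim[2], nb = xdim[3];
  int oy = out_dim(ny, k, stride, pad);
  int ox = out_dim(nx, k, stride, pad);
  const int k2 = k * k, R = k2 * ci;
  const long S = (long)oy * ox, N = S * nb;

  arma::fmat colsT(N, R);
  im2col2d(x.begin(), ny, nx, ci, nb, k, stride, pad, oy, ox, colsT);
  arma::fmat Wt(R, co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) Wt(r, o) = (float)w[r + (long)R * o];
  arma::fmat Yt = colsT * Wt;  // N x co; rows ordered (S, batch)

  NumericVector y((long)S * co * nb);
  for (int o = 0; o < co; ++o) {
    const float* yo = Yt.colptr(o);
    double bo = b[o];
    for (int bI = 0; bI < nb; ++bI) {
      double* dst = y.begin() + S * (o + (long)co * bI);
      const float* src = yo + S * bI;
      for (long s = 0; s < S; ++s) dst[s] = src[s] + bo;
    }
  }
  y.attr("dim") = IntegerVector::create(oy, ox, co, nb);
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, int k, int co,
                         int stride, int pad, NumericVector dy) {
  int ny = xdim[0], nx = xdim[1], ci = xdim[2], nb = xdim[3];
  int oy = out_dim(ny, k, stride, pad);
  int ox = out_dim(nx, k, stride, pad);
  const int k2 = k * k, R = k2 * ci;
  const long S = (long)oy * ox, N = S * nb;

  arma::fmat colsT(N, R);
  im2col2d(x.begin(), ny, nx, ci, nb, k, stride, pad, oy, ox, colsT);

  arma::fmat D(N, co);
  NumericVector dbv(co);
  for (int o = 0; o < co; ++o) {
    float* dcol = D.colptr(o);
    double acc = 0;
    for (int bI = 0; bI < nb; ++bI) {
      const double* src = dy.begin() + S * (o + (long)co * bI);
      float* dst = dcol + S * bI;
      for (long s = 0; s < S; ++s) { dst[s] = (float)src[s]; acc += src[s]; }
    }
    dbv[o] = acc;
  }

  arma::fmat dW = colsT.t() * D;   // R x co
  arma::fmat Wt(R, co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) Wt(r, o) = (float)w[r + (long)R * o];
  arma::fmat dcolsT = D * Wt.t();  // N x R

  NumericVector dx((long)ny * nx * ci * nb);
  double* dxp = dx.begin();
  for (int c = 0; c < ci; ++c)
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        int r = ky + k * kx + k2 * c;
        const float* col = dcolsT.colptr(r);
        for (int bI = 0; bI < nb; ++bI) {
          double* dxc = dxp + (long)bI * ny * nx * ci + (long)c * ny * nx;
          long j = S * bI;
          for (int xi = 0; xi < ox; ++xi) {
            int xx = xi * stride - pad + kx;
            if (xx < 0 || xx >= nx) { j += oy; continue; }
            double* base = dxc + (long)ny * xx;
            for (int yi = 0; yi < oy; ++yi) {
              int yy = yi * stride - pad + ky;
              if (yy >= 0 && yy < ny) base[yy] += col[j];
              ++j;
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(ny, nx, ci, nb);

  NumericVector dwv((long)R * co);
  for (int o = 0; o < co; ++o)
    for (int r = 0; r < R; ++r) dwv[r + (long)R * o] = dW(r, o);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// ---------- nearest-neighbour upsampling ----------

// x: [nz,ny,nx,C] (3D, nd=3) or [ny,nx,C,N] (2D, nd=2); integer factor f on
// the spatial axes only.
// [[Rcpp::export]]
NumericVector upsample_nearest_cpp(NumericVector x, IntegerVector xdim,
                                   int f, int nd) {
  if (nd == 3) {
    int nz = xdim[0], ny = xdim[1], nx = xdim[2], C = xdim[3];
    int oz = nz * f, oy = ny * f, ox = nx * f;
    NumericVector y((long)oz * oy * ox * C);
    for (int c = 0; c < C; ++c)
      for (int xi = 0; xi < ox; ++xi)
        for (int yi = 0; yi < oy; ++yi) {
          const double* src = x.begin() +
            (long)(xi / f) * nz * ny + (long)(yi / f) * nz +
            (long)c * nz * ny * nx;
          double* dst = y.begin() +
            (long)xi * oz * oy + (long)yi * oz + (long)c * oz * oy * ox;
          for (int zi = 0; zi < oz; ++zi) dst[zi] = src[zi / f];
        }
    y.attr("dim") = IntegerVector::create(oz, oy, ox, C);
    return y;
  }
  int ny = xdim[0], nx = xdim[1], C = xdim[2], nb = xdim[3];
  int oy = ny * f, ox = nx * f;
  NumericVector y((long)oy * ox * C * nb);
  for (long cb = 0; cb < (long)C * nb; ++cb)
    for (int xi = 0; xi < ox; ++xi) {
      const double* src = x.begin() + (long)(xi / f) * ny + cb * ny * nx;
      double* dst = y.begin() + (long)xi * oy + cb * oy * ox;
      for (int yi = 0; yi < oy; ++yi) dst[yi] = src[yi / f];
    }
  y.attr("dim") = IntegerVector::create(oy, ox, C, nb);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_nearest_backward_cpp(NumericVector dy, IntegerVector ydim,
                                            int f, int nd) {
  if (nd == 3) {
    int oz = ydim[0], oy = ydim[1], ox = ydim[2], C = ydim[3];
    int nz = oz / f, ny = oy / f, nx = ox / f;
    NumericVector dx((long)nz * ny * nx * C);
    for (int c = 0; c < C; ++c)
      for (int xi = 0; xi < ox; ++xi)
        for (int yi = 0; yi < oy; ++yi) {
          const double* src = dy.begin() +
            (long)xi * oz * oy + (long)yi * oz + (long)c * oz * oy * ox;
          double* dst = dx.begin() +
            (long)(xi / f) * nz * ny + (long)(yi / f) * nz +
            (long)c * nz * ny * nx;
          for (int zi = 0; zi < oz; ++zi) dst[zi / f] += src[zi];
        }
    dx.attr("dim") = IntegerVector::create(nz, ny, nx, C);
    return dx;
  }
  int oy = ydim[0], ox = ydim[1], C = ydim[2], nb = ydim[3];
  int ny = oy / f, nx = ox / f;
  NumericVector dx((long)ny * nx * C * nb);
  for (long cb = 0; cb < (long)C * nb; ++cb)
    for (int xi = 0; xi < ox; ++xi) {
      const double* src = dy.begin() + (long)xi * oy + cb * oy * ox;
      double* dst = dx.begin() + (long)(xi / f) * ny + cb * ny * nx;
      for (int yi = 0; yi < oy; ++yi) dst[yi / f] += src[yi];
    }
  dx.attr("dim") = IntegerVector::create(ny, nx, C, nb);
  return dx;
}

// Block-average pooling of a [nz,ny,nx,C] tensor by integer factors per axis.
// [[Rcpp::export]]
NumericVector avgpool3d_cpp(NumericVector x, IntegerVector xdim,
                            int fz, int fy, int fx) {
  int nz = xdim[0], ny = xdim[1], nx = xdim[2], C = xdim[3];
  int oz = nz / fz, oy = ny / fy, ox = nx / fx;
  NumericVector y((long)oz * oy * ox * C);
  double inv = 1.0 / ((double)fz * fy * fx);
  for (int c = 0; c < C; ++c)
    for (int xi = 0; xi < ox; ++xi)
      for (int yi = 0; yi < oy; ++yi)
        for (int zi = 0; zi < oz; ++zi) {
          double s = 0.0;
          for (int ax = 0; ax < fx; ++ax)
            for (int ay = 0; ay < fy; ++ay)
              for (int az = 0; az < fz; ++az)
                s += x[(zi * fz + az) + (long)nz * ((yi * fy + ay) + (long)ny * ((xi * fx + ax) + (long)nx * c))];
          y[zi + (long)oz * (yi + (long)oy * (xi + (long)ox * c))] = s * inv;
        }
  y.attr("dim") = IntegerVector::create(oz, oy, ox, C);
  return y;
}
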
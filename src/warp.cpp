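// Spatial transformer utilities: trilinear/nearest warping by a dense
// displacement field, the field gradient of the warp, field composition,
// field/volume resizing and affine resampling.
//
// Displacement convention: out(x) = in(x + u(x)), u in voxel units of the
// grid it lives on, component order (dz, dy, dx), field shape [nz,ny,nx,3].
// Out-of-bounds reads return the fill value (trilinear mixes fill into
// partially out-of-bounds stencils).

#include <Rcpp.h>
using namespace Rcpp;

static inline double vox(const double* v, int nz, int ny, int nx,
                         int z, int y, int x, double fill) {
  if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return fill;
  return v[z + (long)nz * (y + (long)ny * x)];
}

static double trilinear(const double* v, int nz, int ny, int nx,
                        double sz, double sy, double sx, double fill) {
  int z0 = (int)std::floor(sz), y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
  double fz = sz - z0, fy = sy - y0, fx = sx - x0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        if (w != 0.0)
          out += w * vox(v, nz, ny, nx, z0 + dz, y0 + dy, x0 + dx, fill);
      }
  return out;
}

// Clamped trilinear (replicate border) used for sampling displacement fields.
static double trilinear_clamp(const double* v, int nz, int ny, int nx,
                              double sz, double sy, double sx) {
  sz = std::min(std::max(sz, 0.0), (double)(nz - 1));
  sy = std::min(std::max(sy, 0.0), (double)(ny - 1));
  sx = std::min(std::max(sx, 0.0), (double)(nx - 1));
  int z0 = std::min((int)std::floor(sz), nz - 2 >= 0 ? nz - 2 : 0);
  int y0 = std::min((int)std::floor(sy), ny - 2 >= 0 ? ny - 2 : 0);
  int x0 = std::min((int)std::floor(sx), nx - 2 >= 0 ? nx - 2 : 0);
  if (nz == 1) z0 = 0;
  if (ny == 1) y0 = 0;
  if (nx == 1) x0 = 0;
  double fz = nz == 1 ? 0.0 : sz - z0, fy = ny == 1 ? 0.0 : sy - y0,
         fx = nx == 1 ? 0.0 : sx - x0;
  double out = 0.0;
  for (int dz = 0; dz <= (nz == 1 ? 0 : 1); ++dz)
    for (int dy = 0; dy <= (ny == 1 ? 0 : 1); ++dy)
      for (int dx = 0; dx <= (nx == 1 ? 0 : 1); ++dx) {
        double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        out += w * v[(z0 + dz) + (long)nz * ((y0 + dy) + (long)ny * (x0 + dx))];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector warp3d_cpp(NumericVector vol, IntegerVector vdim,
                         NumericVector field, int nearest, double fill) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  long N = (long)nz * ny * nx;
  NumericVector out(N);
  const double* v = vol.begin();
  const double* u = field.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        double sz = z + u[i], sy = y + u[i + N], sx = x + u[i + 2 * N];
        if (nearest) {
          int zi = (int)std::round(sz), yi = (int)std::round(sy), xi = (int)std::round(sx);
          out[i] = vox(v, nz, ny, nx, zi, yi, xi, fill);
        } else {
          out[i] = trilinear(v, nz, ny, nx, sz, sy, sx, fill);
        }
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}

// Gradient of sum(dout * warp(vol, field)) with respect to the field.
// [[Rcpp::export]]
NumericVector warp3d_backward_field_cpp(NumericVector vol, IntegerVector vdim,
                                        NumericVector field, NumericVector dout,
                                        double fill) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  long N = (long)nz * ny * nx;
  NumericVector dfield(3 * N);
  const double* v = vol.begin();
  const double* u = field.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        double g = dout[i];
        if (g == 0.0) continue;
        double sz = z + u[i], sy = y + u[i + N], sx = x + u[i + 2 * N];
        int z0 = (int)std::floor(sz), y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double fz = sz - z0, fy = sy - y0, fx = sx - x0;
        double dz_acc = 0, dy_acc = 0, dx_acc = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              double val = vox(v, nz, ny, nx, z0 + dz, y0 + dy, x0 + dx, fill);
              double wz = dz ? 1.0 : -1.0;
              double wy = dy ? 1.0 : -1.0;
              double wx = dx ? 1.0 : -1.0;
              dz_acc += wz * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx) * val;
              dy_acc += (dz ? fz : 1 - fz) * wy * (dx ? fx : 1 - fx) * val;
              dx_acc += (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * wx * val;
            }
        dfield[i] = g * dz_acc;
        dfield[i + N] = g * dy_acc;
        dfield[i + 2 * N] = g * dx_acc;
      }
  dfield.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return dfield;
}

// compose(f_outer, f_inner)(x) = f_inner(x) + f_outer(x + f_inner(x)).
// warp(img, compose(fo, fi)) == warp(warp(img, fo), fi) up to interpolation.
// [[Rcpp::export]]
NumericVector compose_fields_cpp(NumericVector f_outer, NumericVector f_inner,
                                 IntegerVector vdim) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  long N = (long)nz * ny * nx;
  NumericVector out(3 * N);
  const double* fo = f_outer.begin();
  const double* fi = f_inner.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = z + (long)nz * (y + (long)ny * x);
        double sz = z + fi[i], sy = y + fi[i + N], sx = x + fi[i + 2 * N];
        for (int c = 0; c < 3; ++c)
          out[i + c * N] = fi[i + c * N] +
            trilinear_clamp(fo + c * N, nz, ny, nx, sz, sy, sx);
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// Resize a displacement field to a new grid, rescaling each component by the
// per-axis zoom so displacements stay in voxel units of the target grid.
// Center-aligned mapping: src = (dst + 0.5) / zoom - 0.5.
// [[Rcpp::export]]
NumericVector field_resize_cpp(NumericVector field, IntegerVector fdim,
                               IntegerVector newdim) {
  int nz = fdim[0], ny = fdim[1], nx = fdim[2];
  int mz = newdim[0], my = newdim[1], mx = newdim[2];
  long N = (long)nz * ny * nx, M = (long)mz * my * mx;
  double zz = (double)mz / nz, zy = (double)my / ny, zx = (double)mx / nx;
  double scale[3] = {zz, zy, zx};
  NumericVector out(3 * M);
  const double* f = field.begin();
  for (int x = 0; x < mx; ++x)
    for (int y = 0; y < my; ++y)
      for (int z = 0; z < mz; ++z) {
        long i = z + (long)mz * (y + (long)my * x);
        double sz = (z + 0.5) / zz - 0.5, sy = (y + 0.5) / zy - 0.5,
               sx = (x + 0.5) / zx - 0.5;
        for (int c = 0; c < 3; ++c)
          out[i + c * M] = scale[c] *
            trilinear_clamp(f + c * N, nz, ny, nx, sz, sy, sx);
      }
  out.attr("dim") = IntegerVector::create(mz, my, mx, 3);
  return out;
}

// General affine resampling in index space: out(x) = vol(A x + t).
// A is 3x3 row-major (rows/cols ordered z,y,x), t length 3.
// [[Rcpp::export]]
NumericVector affine_sample_cpp(NumericVector vol, IntegerVector vdim,
                                IntegerVector odim, NumericVector A,
                                NumericVector t, double fill, int nearest) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  int oz = odim[0], oy = odim[1], ox = odim[2];
  NumericVector out((long)oz * oy * ox);
  const double* v = vol.begin();
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        double sz = A[0] * z + A[1] * y + A[2] * x + t[0];
        double sy = A[3] * z + A[4] * y + A[5] * x + t[1];
        double sx = A[6] * z + A[7] * y + A[8] * x + t[2];
        long i = z + (long)oz * (y + (long)oy * x);
        if (nearest) {
          int zi = (int)std::round(sz), yi = (int)std::round(sy), xi = (int)std::round(sx);
          out[i] = vox(v, nz, ny, nx, zi, yi, xi, fill);
        } else {
          out[i] = trilinear(v, nz, ny, nx, sz, sy, sx, fill);
        }
      }
  out.attr("dim") = IntegerVector::create(oz, oy, ox);
  return out;
}

// Diffusion regularizer: mean over (voxel, component, direction) of squared
// forward differences, valid positions only. Returns loss and gradient.
// [[Rcpp::export]]
List smoothness_loss_cpp(NumericVector field, IntegerVector fdim, int want_grad) {
  int nz = fdim[0], ny = fdim[1], nx = fdim[2];
  long N = (long)nz * ny * nx;
  const double* u = field.begin();
  NumericVector grad(want_grad ? 3 * N : 0);
  double acc = 0.0;
  long nterms = 0;
  long strides[3] = {1, (long)nz, (long)nz * ny};
  int dims[3] = {nz, ny, nx};
  for (int c = 0; c < 3; ++c) {
    const double* uc = u + c * N;
    double* gc = want_grad ? grad.begin() + c * N : nullptr;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          long i = z + (long)nz * (y + (long)ny * x);
          int pos[3] = {z, y, x};
          for (int d = 0; d < 3; ++d) {
            if (pos[d] + 1 >= dims[d]) continue;
            double diff = uc[i + strides[d]] - uc[i];
            acc += diff * diff;
            ++nterms;
            if (want_grad) {
              gc[i + strides[d]] += 2.0 * diff;
              gc[i] -= 2.0 * diff;
            }
          }
        }
  }
  double denom = nterms > 0 ? (double)nterms : 1.0;
  double loss = acc / denom;
  if (want_grad) {
    for (long i = 0; i < 3 * N; ++i) grad[i] /= denom;
    grad.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
    return List::create(_["loss"] = loss, _["grad"] = grad);
  }
  return List::create(_["loss"] = loss);
}
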
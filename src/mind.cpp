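// Modality-independent neighborhood descriptor (MIND) and the L1 descriptor
// dissimilarity loss, with an analytic gradient with respect to the second
// image (needed because the loss drives network training).
//
// Construction, per offset o in the offset set:
//   Dp(x,o) = sum_q w_q (I(x+q) - I(x+q+o))^2   (Gaussian-weighted patch SSD,
//             replicate padding at the borders)
//   V(x)    = max(mean_o Dp(x,o), eps),  eps = eps_rel * mean_x mean_o Dp
//   D(x,o)  = exp(-(Dp(x,o) - min_o Dp(x,o)) / V(x))   in (0, 1], max = 1
// (subtracting the per-voxel min is the per-voxel max-normalization).
//
// Loss(i1, i2) = mean over region voxels and offsets of |D1(x,o) - D2(x,o)|.

#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct MindGeom {
  int nz, ny, nx, K, P;
  const int* off;    // K x 3 (column-major from R: off[k], off[k+K], off[k+2K])
  const int* patch;  // P x 3
  const double* pw;  // P
};

static inline long cidx(const MindGeom& g, int z, int y, int x) {
  return clampi(z, 0, g.nz - 1) +
         (long)g.nz * (clampi(y, 0, g.ny - 1) +
         (long)g.ny * clampi(x, 0, g.nx - 1));
}

// Fill Dp (N x K, column per offset) for one image.
static void patch_ssd(const double* img, const MindGeom& g, std::vector<double>& Dp) {
  long N = (long)g.nz * g.ny * g.nx;
  for (int k = 0; k < g.K; ++k) {
    int oz = g.off[k], oy = g.off[k + g.K], ox = g.off[k + 2 * g.K];
    double* col = Dp.data() + (long)k * N;
    for (int x = 0; x < g.nx; ++x)
      for (int y = 0; y < g.ny; ++y)
        for (int z = 0; z < g.nz; ++z) {
          long i = z + (long)g.nz * (y + (long)g.ny * x);
          double acc = 0.0;
          for (int p = 0; p < g.P; ++p) {
            int qz = g.patch[p], qy = g.patch[p + g.P], qx = g.patch[p + 2 * g.P];
            double a = img[cidx(g, z + qz, y + qy, x + qx)];
            double b = img[cidx(g, z + qz + oz, y + qy + oy, x + qx + ox)];
            acc += g.pw[p] * (a - b) * (a - b);
          }
          col[i] = acc;
        }
  }
}

// Per-voxel descriptor channels from Dp; also records V and the argmin
// offset and whether V was floored (needed by the gradient).
static void channels_from_Dp(const std::vector<double>& Dp, long N, int K,
                             double eps_rel,
                             std::vector<double>& C, std::vector<double>& V,
                             std::vector<int>& omin, std::vector<char>& floored) {
  double gmean = 0.0;
  for (long i = 0; i < (long)K * N; ++i) gmean += Dp[i];
  gmean /= (double)K * N;
  double eps = std::max(eps_rel * gmean, 1e-300);
  eps = std::max(eps, 1e-12);
  for (long i = 0; i < N; ++i) {
    double dbar = 0.0, dmin = Dp[i];
    int am = 0;
    for (int k = 0; k < K; ++k) {
      double d = Dp[i + (long)k * N];
      dbar += d;
      if (d < dmin) { dmin = d; am = k; }
    }
    dbar /= K;
    double v = dbar;
    char fl = 0;
    if (v < eps) { v = eps; fl = 1; }
    V[i] = v; omin[i] = am; floored[i] = fl;
    for (int k = 0; k < K; ++k)
      C[i + (long)k * N] = std::exp(-(Dp[i + (long)k * N] - dmin) / v);
  }
}

// [[Rcpp::export]]
NumericVector mind_descriptor_cpp(NumericVector img, IntegerVector vdim,
                                  IntegerMatrix offsets, IntegerMatrix patch,
                                  NumericVector pweights, double eps_rel) {
  MindGeom g{vdim[0], vdim[1], vdim[2], offsets.nrow(), patch.nrow(),
             offsets.begin(), patch.begin(), pweights.begin()};
  long N = (long)g.nz * g.ny * g.nx;
  std::vector<double> Dp((long)g.K * N), C((long)g.K * N), V(N);
  std::vector<int> omin(N);
  std::vector<char> floored(N);
  patch_ssd(img.begin(), g, Dp);
  channels_from_Dp(Dp, N, g.K, eps_rel, C, V, omin, floored);
  NumericVector out((long)g.K * N);
  std::copy(C.begin(), C.end(), out.begin());
  out.attr("dim") = IntegerVector::create(g.nz, g.ny, g.nx, g.K);
  return out;
}

// [[Rcpp::export]]
List mind_loss_cpp(NumericVector i1, NumericVector i2, IntegerVector vdim,
                   IntegerMatrix offsets, IntegerMatrix patch,
                   NumericVector pweights, double eps_rel,
                   NumericVector region, int want_grad) {
  MindGeom g{vdim[0], vdim[1], vdim[2], offsets.nrow(), patch.nrow(),
             offsets.begin(), patch.begin(), pweights.begin()};
  long N = (long)g.nz * g.ny * g.nx;
  int K = g.K;
  bool has_region = region.size() == N;

  std::vector<double> Dp1((long)K * N), C1((long)K * N), V1(N);
  std::vector<double> Dp2((long)K * N), C2((long)K * N), V2(N);
  std::vector<int> om1(N), om2(N);
  std::vector<char> fl1(N), fl2(N);
  patch_ssd(i1.begin(), g, Dp1);
  patch_ssd(i2.begin(), g, Dp2);
  channels_from_Dp(Dp1, N, K, eps_rel, C1, V1, om1, fl1);
  channels_from_Dp(Dp2, N, K, eps_rel, C2, V2, om2, fl2);

  long nreg = 0;
  double loss = 0.0;
  for (long i = 0; i < N; ++i) {
    if (has_region && region[i] <= 0.5) continue;
    ++nreg;
    for (int k = 0; k < K; ++k)
      loss += std::fabs(C1[i + (long)k * N] - C2[i + (long)k * N]);
  }
  if (nreg == 0) stop("empty region in MIND loss");
  double denom = (double)nreg * K;
  loss /= denom;
  if (!want_grad) return List::create(_["loss"] = loss);

  // s_m(x): dLoss/dDp2_m(x)
  std::vector<double> S((long)K * N, 0.0);
  for (long i = 0; i < N; ++i) {
    if (has_region && region[i] <= 0.5) continue;
    double T1 = 0.0, T2 = 0.0, v = V2[i];
    for (int k = 0; k < K; ++k) {
      double c1 = C1[i + (long)k * N], c2 = C2[i + (long)k * N];
      double gk = (c2 > c1 ? 1.0 : (c2 < c1 ? -1.0 : 0.0)) / denom; // d|c1-c2|/dc2
      double A = -std::log(std::max(c2, 1e-300)); // (Dp - Dmin)/V
      T1 += gk * c2;
      T2 += gk * c2 * A;
      S[i + (long)k * N] = -gk * c2 / v;
    }
    S[i + (long)om2[i] * N] += T1 / v;
    if (!fl2[i]) {
      double add = T2 / (K * v);
      for (int k = 0; k < K; ++k) S[i + (long)k * N] += add;
    }
  }

  // Scatter through the patch SSD terms of i2.
  NumericVector grad(N);
  const double* I2 = i2.begin();
  for (int k = 0; k < K; ++k) {
    int oz = g.off[k], oy = g.off[k + K], ox = g.off[k + 2 * K];
    const double* sk = S.data() + (long)k * N;
    for (int x = 0; x < g.nx; ++x)
      for (int y = 0; y < g.ny; ++y)
        for (int z = 0; z < g.nz; ++z) {
          long i = z + (long)g.nz * (y + (long)g.ny * x);
          double s = sk[i];
          if (s == 0.0) continue;
          for (int p = 0; p < g.P; ++p) {
            int qz = g.patch[p], qy = g.patch[p + g.P], qx = g.patch[p + 2 * g.P];
            long a = cidx(g, z + qz, y + qy, x + qx);
            long b = cidx(g, z + qz + oz, y + qy + oy, x + qx + ox);
            double d = 2.0 * g.pw[p] * (I2[a] - I2[b]) * s;
            grad[a] += d;
            grad[b] -= d;
          }
        }
  }
  grad.attr("dim") = IntegerVector::create(g.nz, g.ny, g.nx);
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
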
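// Windowed SSIM, computed per axial slice with a uniform square window and
// averaged over all window centers and slices. Windows are clipped at the
// slice borders (uniform weights over the in-bounds part).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double ssim_slices_cpp(NumericVector i1, NumericVector i2, IntegerVector dim,
                       int radius, double c1, double c2) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double acc = 0.0;
  long cnt = 0;
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
        int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        double s1 = 0, s2 = 0, s11 = 0, s22 = 0, s12 = 0;
        int n = 0;
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy) {
            long i = z + (long)nz * (yy + (long)ny * xx);
            double a = i1[i], b = i2[i];
            s1 += a; s2 += b; s11 += a * a; s22 += b * b; s12 += a * b;
            ++n;
          }
        double m1 = s1 / n, m2 = s2 / n;
        double v1 = s11 / n - m1 * m1, v2 = s22 / n - m2 * m2;
        double cov = s12 / n - m1 * m2;
        double num = (2 * m1 * m2 + c1) * (2 * cov + c2);
        double den = (m1 * m1 + m2 * m2 + c1) * (v1 + v2 + c2);
        acc += num / den;
        ++cnt;
      }
  }
  return acc / cnt;
}
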
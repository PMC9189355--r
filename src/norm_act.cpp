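// Fused instance-norm and leaky-ReLU kernels (the R-level versions spend
// their time in temporary allocations).

#include <Rcpp.h>
using namespace Rcpp;

// x viewed as S x G (spatial x groups); gamma/beta length C with G = C*rep.
// [[Rcpp::export]]
List instnorm_forward_cpp(NumericVector x, int S, int G, int C,
                          NumericVector gamma, NumericVector beta) {
  NumericVector y(x.size()), xhat(x.size()), istd(G);
  for (int g = 0; g < G; ++g) {
    const double* xs = x.begin() + (long)g * S;
    double m = 0, v = 0;
    for (int i = 0; i < S; ++i) m += xs[i];
    m /= S;
    for (int i = 0; i < S; ++i) { double d = xs[i] - m; v += d * d; }
    v /= S;
    double is = 1.0 / std::sqrt(v + 1e-5);
    istd[g] = is;
    double ga = gamma[g % C], be = beta[g % C];
    double* ys = y.begin() + (long)g * S;
    double* hs = xhat.begin() + (long)g * S;
    for (int i = 0; i < S; ++i) {
      double h = (xs[i] - m) * is;
      hs[i] = h;
      ys[i] = ga * h + be;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List instnorm_backward_cpp(NumericVector dy, NumericVector xhat,
                           NumericVector istd, int S, int G, int C,
                           NumericVector gamma) {
  NumericVector dx(dy.size()), dg(C), db(C);
  for (int g = 0; g < G; ++g) {
    const double* ds = dy.begin() + (long)g * S;
    const double* hs = xhat.begin() + (long)g * S;
    double ga = gamma[g % C];
    double sum_d = 0, sum_dh = 0, sdg = 0, sdb = 0;
    for (int i = 0; i < S; ++i) {
      double dxh = ds[i] * ga;
      sum_d += dxh;
      sum_dh += dxh * hs[i];
      sdg += ds[i] * hs[i];
      sdb += ds[i];
    }
    dg[g % C] += sdg;
    db[g % C] += sdb;
    double is = istd[g];
    double* xs = dx.begin() + (long)g * S;
    for (int i = 0; i < S; ++i) {
      double dxh = ds[i] * ga;
      xs[i] = (dxh - sum_d / S - hs[i] * sum_dh / S) * is;
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export]]
List lrelu_forward_cpp(NumericVector x, double slope) {
  NumericVector y(x.size());
  LogicalVector neg(x.size());
  for (long i = 0; i < (long)x.size(); ++i) {
    if (x[i] < 0) { y[i] = slope * x[i]; neg[i] = true; }
    else y[i] = x[i];
  }
  return List::create(_["y"] = y, _["neg"] = neg);
}

// [[Rcpp::export]]
NumericVector lrelu_backward_cpp(NumericVector dy, LogicalVector neg,
                                 double slope) {
  NumericVector dx(dy.size());
  for (long i = 0; i < (long)dy.size(); ++i)
    dx[i] = neg[i] ? slope * dy[i] : dy[i];
  return dx;
}
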
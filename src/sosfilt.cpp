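#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-sections) filtering along columns,
// transposed direct form II, zero initial conditions. sos: n_sections x 6
// (b0 b1 b2 a0 a1 a2), a0 == 1.
// [[Rcpp::export(name = ".sos_filter_cpp")]]
NumericMatrix sos_filter_cpp(NumericMatrix x, NumericMatrix sos) {
  const int n = x.nrow(), k = x.ncol(), ns = sos.nrow();
  NumericMatrix y(n, k);
  std::vector<double> z1(ns), z2(ns);
  for (int j = 0; j < k; ++j) {
    std::fill(z1.begin(), z1.end(), 0.0);
    std::fill(z2.begin(), z2.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      for (int s = 0; s < ns; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        const double w = b0 * v + z1[s];
        z1[s] = b1 * v - a1 * w + z2[s];
        z2[s] = b2 * v - a2 * w;
        v = w;
      }
      y(i, j) = v;
    }
  }
  return y;
}

// Burg AR fit of a demeaned series; returns prediction coefficients a
// (lag 1..p) in the convention x_t = sum_j a_j x_{t-j} + e_t
// (same convention as stats::ar.burg's $ar).
// [[Rcpp::export(name = ".ar_burg_cpp")]]
NumericVector ar_burg_cpp(NumericVector x, int p) {
  const int N = x.size();
  std::vector<double> A(p + 1, 0.0);
  A[0] = 1.0;
  std::vector<double> f(x.begin(), x.end()), b(x.begin(), x.end());
  double Dk = 0.0;
  for (int i = 0; i < N; ++i) Dk += 2.0 * f[i] * f[i];
  Dk -= f[0] * f[0] + b[N - 1] * b[N - 1];
  for (int k = 0; k < p; ++k) {
    double mu = 0.0;
    for (int n = 0; n <= N - k - 2; ++n) mu += f[n + k + 1] * b[n];
    mu = Dk > 0 ? -2.0 * mu / Dk : 0.0;
    for (int n = 0; n <= (k + 1) / 2; ++n) {
      const double t1 = A[n] + mu * A[k + 1 - n];
      const double t2 = A[k + 1 - n] + mu * A[n];
      A[n] = t1;
      A[k + 1 - n] = t2;
    }
    for (int n = 0; n <= N - k - 2; ++n) {
      const double t1 = f[n + k + 1] + mu * b[n];
      const double t2 = b[n] + mu * f[n + k + 1];
      f[n + k + 1] = t1;
      b[n] = t2;
    }
    Dk = (1.0 - mu * mu) * Dk - f[k + 1] * f[k + 1] -
      b[N - k - 2] * b[N - k - 2];
  }
  NumericVector a(p);
  for (int j = 1; j <= p; ++j) a[j - 1] = -A[j];
  return a;
}

// Forward AR(p) extrapolation: given the last p centered samples (most
// recent last) and AR coefficients a (lag 1..p), predict npad steps ahead.
// [[Rcpp::export(name = ".ar_predict_cpp")]]
NumericVector ar_predict_cpp(NumericVector tail_vals, NumericVector a,
                             int npad) {
  const int p = a.size();
  std::vector<double> buf(tail_vals.begin(), tail_vals.end());
  NumericVector out(npad);
  for (int i = 0; i < npad; ++i) {
    double v = 0.0;
    for (int k = 0; k < p; ++k) v += a[k] * buf[p - 1 - k];
    out[i] = v;
    buf.erase(buf.begin());
    buf.push_back(v);
  }
  return out;
}
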